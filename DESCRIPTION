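Package: hichipml
Title: Predicting TAD State from Chromatin Marks via Transitional Gamma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes a per-bin chromatin-folding target ("transitional gamma")
    from Hi-C contact maps by a dynamic-programming TAD segmentation swept over
    a grid of resolution parameters, and predicts that target from chromatin-mark
    signal tracks with constant, regularized-linear, gradient-boosted and
    windowed bidirectional-LSTM regressors trained under a weighted
    mean-squared-error loss. Includes synthetic planted-TAD data generators,
    bedGraph/BED input-output, repeated-split cross-validation, hyperparameter
    scans and use-one/drop-one feature-importance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
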