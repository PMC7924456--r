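---
title: "Transitional gamma: a per-bin TAD-state target and its prediction from chromatin marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transitional gamma: a per-bin TAD-state target and its prediction from chromatin marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hichipml)
```

## The segmentation model

A Hi-C contact map is a symmetric non-negative matrix $A$ of interaction
frequencies between equal-width genomic bins (20 kb by default here, the
working resolution for fly-sized genomes). The caller scores an interval of
bins $[k, l]$ with $d = l - k + 1$ by the scaled intra-interval contact sum

$$ s_\gamma(k, l) = \frac{\sum_{k \le i \le j \le l} A_{ij}}{d^{\,\gamma}},
\qquad q_\gamma(k, l) = s_\gamma(k, l) - \mu_\gamma(d), $$

where $\mu_\gamma(d)$ is the mean of $s_\gamma$ over all length-$d$
intervals of the same chromosome. A segmentation maximizes
$\sum \max(q_\gamma, 0)$ over disjoint intervals via the prefix dynamic
program $\mathrm{OPT}(l) = \max\bigl(\mathrm{OPT}(l-1),\,
\max_k [\mathrm{OPT}(k-1) + q_\gamma(k,l)^+]\bigr)$; only intervals with
$q > 0$ are emitted as domains. Each bin is then annotated TAD (domain
interior), boundary (first/last bin of a domain; a length-1 domain is a
lone boundary) or inter-TAD (outside every domain). The resolution
parameter $\gamma$ penalizes long intervals, so larger $\gamma$ produces
smaller domains.

Choices worth stating explicitly, since segmentation conventions differ
between implementations:

* the interval sum includes the diagonal ($i = j$ allowed), and the length
  normalization is $d^\gamma$ with $d$ the number of bins; a length-1
  interval's raw score is $A_{ii}$;
* $\mu_\gamma(d)$ is the simple mean over all $n-d+1$ intervals of length
  $d$; a length occurring once contributes its own value;
* scores are computed on raw counts by default; a `log1p` transform is
  available (`segment_map(..., transform = "log1p")`) for heavy-tailed
  count distributions;
* tie-breaking in the DP is deterministic: on exact ties "no new domain"
  wins, then the smaller start index. A single optimal segmentation is
  used; near-optimal ensembles are out of scope.

Because $q_\gamma = (S_d - \overline{S_d})\,d^{-\gamma}$, the *sign* of an
interval's quality is independent of $\gamma$; $\gamma$ only reweights
lengths. Two consequences are load-bearing for everything downstream.
First, adding a constant to all matrix entries leaves $q$ unchanged (the
length-matched mean absorbs it), which the tests assert. Second, as
$\gamma \to \infty$ the optimum degenerates to the shortest
positive-quality intervals, which explains exactly when "never
transitioning" bins exist (below).

The per-gamma pass is $O(n^2)$ after an $O(n^2)$ prefix-sum precompute and
is implemented in C++ (Rcpp); a 1001-point sweep of a 150-bin map takes a
fraction of a second. A brute-force oracle (`segment_bruteforce()`)
exhaustively enumerates all disjoint subsets of positive-quality intervals
and is used in the tests to certify DP optimality on maps up to 12 bins.

## The transitional-gamma target

The sweep runs the caller over an inclusive grid (default 0 to 10 in steps
of 0.01; the grid is built by integer multiplication of the step, so there
is no floating-point accumulation). For each bin, the target is the
*smallest* grid $\gamma$ at which the bin's annotation is boundary or
inter-TAD — a first-crossing minimum, not a monotone threshold: a bin may
revert to TAD at higher $\gamma$, but the minimum is what is recorded. Bins
annotated TAD at every grid value receive the cap `gamma_max`, which
defaults to the grid stop (10): the cap is a statement that the bin was
never observed outside a TAD, not a measurement at $\gamma = 10$. With the
default grid the target lives in $\{0, 0.01, \dots, 10\}$ and its
distribution is strongly skewed: most bins transition below $\gamma \approx
3$, with a spike at the cap.

When do cap bins exist? At large $\gamma$ the optimum consists of the
shortest positive-quality intervals. On a noise-free tiling of planted
TADs, within-TAD *adjacent pairs* always have positive quality, so every
bin eventually becomes a pair boundary and no bin caps. Cap bins arise when
a bin's flanking pairs (and its own diagonal) are locally sub-average while
a containing interval of three or more bins stays super-average — in data
terms, a strong inner-TAD bin whose skip-one contact is strong relative to
its adjacent contacts. Under realistic noise a small fraction of bins has
this property, which matches the empirically observed minor cap fraction.
The acceptance machinery therefore simulates maps (high enrichment,
realistic noise) and redraws from derived sub-seeds until the generated map
actually contains such an always-TAD block before computing $\alpha$.

Per-chromosome sweeps are independent and concatenated in chromosome order;
windows never cross chromosomes.

## The loss

With targets this skewed, plain MSE is dominated by the rare high-target
bins. Training and headline evaluation therefore use

$$ \mathrm{wMSE} = \frac{1}{N} \sum_i (y_i - \hat y_i)^2\,
   \frac{\alpha - y_i}{\alpha}, \qquad \alpha = \max_i y_i + 1 . $$

The $+1$ keeps every weight strictly positive; for a cap-10 target,
$\alpha = 11$ and the weight ranges from $1$ (at $y = 0$, where wMSE
coincides with MSE) down to $1/11$. `wmse()` refuses $y \ge \alpha$, where
the weight would be non-positive. wMSE $\le$ MSE always holds for
non-negative targets.

## Models

All model inputs are per-mark z-scored signals. Following the reference
preprocessing behaviour, standardization uses the *population* variance and
is fitted on **all** bins before splitting; this leaks distributional
information across splits, so `standardize_features(center=, scale=)`
accepts previously fitted statistics for the orthodox fit-on-train
alternative. Zero-variance marks are centred, left unscaled and flagged.

* **Constant**: the training-target mean. Train $R^2 = 0$ by construction.
* **Linear** (`fit_linear`): OLS via QR when unpenalized (minimum-norm
  pseudoinverse with a warning if singular); otherwise glmnet with the
  per-penalty strengths $(\ell_1, \ell_2)$ in the
  $\tfrac{1}{2n}\mathrm{RSS} + \ell_1\lVert\beta\rVert_1 +
  \tfrac{\ell_2}{2}\lVert\beta\rVert_2^2$ convention, mapped as
  $\lambda = \ell_1 + \ell_2$, $\alpha_{\mathrm{mix}} =
  \ell_1/(\ell_1+\ell_2)$. The scanned operating point is 0.2 for either
  penalty. Coefficients are exposed for importance ranking.
* **Gradient boosting** (`fit_gboost`): least-squares trees (xgboost,
  single-threaded for determinism), reference operating points 100 trees ×
  depth 3 and 250 × depth 4 at learning rate 0.01. Training on plain least
  squares is deliberate — wMSE is the *metric*; an optional
  `weight_by_target` flag trains with weights $(\alpha-y)/\alpha$ for an
  exact match, off by default.
* **biLSTM** (`fit_bilstm`): one bidirectional LSTM layer (`units` hidden
  units per direction) reads the window of $t$ consecutive bins; the two
  final hidden states are concatenated into a single linear output that
  predicts the *middle* bin's target (index $\lfloor t/2 \rfloor$,
  0-based). The loss is wMSE with the dataset $\alpha$; the optimizer is
  Adam. The network sees only neighbouring *features*, never neighbouring
  targets. It is implemented directly on matrix algebra with explicit
  backpropagation through time — at these sizes ($t \le 10$, a handful of
  marks, $\le$ a few hundred units) this trains in seconds and keeps the
  dependency surface small; the analytic gradients are verified against
  finite differences in the tests.

Unstated training details fixed here (documented defaults, not tuned per
experiment): batch size 128, learning rate $10^{-3}$, max 100 epochs,
early stopping on validation wMSE with patience 10 and best-weight
restoration, forget-gate bias initialized at 1, Glorot-uniform weights.
One integer seed drives initialization and shuffling, so fits are exactly
reproducible.

## Windows and splits

Windows are $t$ consecutive same-chromosome bins with the middle bin's
target as label; edge bins that cannot centre a full window are dropped
rather than padded, so every label is honestly observed. $t = 1$ reduces
exactly to per-bin regression, which is the input mode of the constant,
linear and boosting models.

The split is 70% train / 20% test / 10% validation over *windows*
(shuffle, then cut at $\lfloor 0.7m \rfloor$ and $\lfloor 0.9m \rfloor$).
Overlapping windows share bins across splits; that mirrors the stated
reference protocol, and a `contiguous_blocks` mode (consecutive genome runs
per split) is provided as the leakage-safe alternative and is what the
context-benefit acceptance check uses. Whether the original protocol split
bins or windows, and padded or dropped edges, is not documented anywhere we
could rely on; both choices here are explicit.

"Cross-validation" (`cross_validate`) is repeated random resplitting
(default 10 rounds, seeds `base + 0..9`) with mean ± sd per metric — a
resampled-split reading of "averaged over ten rounds"; k-fold is not what
the protocol describes and is not implemented.

## Feature importance

Two retraining procedures (`use_one_importance`, `drop_one_importance`),
both from scratch per configuration, no permutation shortcut:

* **use-one**: train on each single mark alone; report wMSE next to an
  all-features row and a constant-baseline row ($n_{\mathrm{marks}} + 2$
  rows).
* **drop-one**: zero one standardized column at a time (zero *is* the
  mark's mean after z-scoring) and retrain on all columns;
  `degradation = wMSE_dropped − wMSE_all` on the test split.

With strongly correlated marks, dropping one of a redundant pair degrades
nothing — a property the tests assert with a planted duplicate — so
use-one and drop-one answer different questions and are reported together.

## The synthetic-data generator

The generator defines this package's study conditions:

* **Contact maps**: planted TADs tile the chromosome (lengths uniform on
  5–10 bins by default, bracketing the typical ~120 kb fly TAD at 20 kb
  resolution; an optional `gap_fraction` inserts unstructured bins so the
  inter-TAD annotation is exercised). Mean contact is
  $(1+|i-j|)^{-\mathrm{decay}}$, times `intra_tad_enrichment` (default 4)
  inside a TAD, with decay exponent 0.8 and additive Gaussian noise
  (default sd 0.5) truncated at 0 — counts are non-negative, so truncation
  rather than an untruncated Gaussian.
* **Mark tracks**: boundary-enriched marks put `effect_size` on boundary
  bins (a Chriz-like insulator profile), interior-enriched marks on
  TAD-interior bins (a broad repressive-mark profile), smoothed by a short
  moving average, plus Gaussian noise; noise marks are i.i.d. Gaussian.
* **Supervised tracks** (`simulate_supervised_track`): i.i.d. Gaussian
  features with a planted odd-length context-window rule,
  $y_i = \mathrm{clip}(\mathrm{offset} + \sum_k w_k x_{i+k-c} +
  \varepsilon, 0, 10)$, the clip range mirroring the target range. The
  optional offset exists because with zero-mean features the clip at 0
  censors half the data; a mid-range offset keeps the planted linear
  weights identifiable, which the linear-recovery check requires.

What the generator does *not* emulate: coverage bias, matrix balancing
(ICE), distance-dependent noise heteroscedasticity, hierarchical/nested
TADs, or any sequence-level signal. Passing tests therefore certify the
algorithmic contracts (optimality, determinism, monotonicity, recovery of
planted structure), not performance on real Hi-C/ChIP data.

## Problem sizes and numeric tolerances

The shipped tests and acceptance checks run at deliberately modest sizes,
chosen as the smallest scales at which each claim is statistically
unambiguous: oracle equivalence on $\le 12$-bin maps (50 seeds, exact to
$10^{-10}$), size–gamma monotonicity on a 200-bin map over a 0.1-step
sweep (1-bin tolerance, allowing noise-driven wiggles), learnability and
context-benefit checks on 5 000-bin supervised tracks with 3 seeds and
median comparisons, and importance recovery on 2 000-bin fixtures. Matrix
symmetry is enforced within $10^{-8}$ on construction and $10^{-6}$ on
dense input (sub-tolerance asymmetry is averaged away); bedGraph round
trips are lossless within $10^{-9}$.

## Known limitations

* The segmentation is a faithful reconstruction of the scoring family the
  transitional-gamma definition needs, not a byte-compatible reimplementation
  of any particular released caller; the contract is behavioural
  (annotation trichotomy, size–gamma monotonicity, DP optimality).
* Multi-resolution consensus, hierarchical TADs, and alternative TAD-state
  scores (insulation score, directionality index) are out of scope.
* The biLSTM is CPU-only and sized for desk-scale genomes (thousands of
  bins); it is not a framework for large architectures.
* Reading cooler/hic binaries and writing bigWig are not supported; dense
  or sparse text matrices and bedGraph/BED are the interchange formats.
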