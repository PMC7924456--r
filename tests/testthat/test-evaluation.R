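test_that("metrics match hand evaluation", {
  ev <- evaluate_predictions(c(0, 2), c(1, 1), 3)
  expect_equal(ev$mse, 1)
  expect_equal(ev$mae, 1)
  expect_equal(ev$r2, 0)
  expect_equal(ev$wmse, 2 / 3)  # (1*3/3 + 1*1/3) / 2
  # perfect prediction
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3), 11)
  expect_equal(ev$mse, 0); expect_equal(ev$mae, 0)
  expect_equal(ev$r2, 1); expect_equal(ev$wmse, 0)
  # zero target variance: R2 undefined with a warning
  expect_warning(ev <- evaluate_predictions(c(2, 2), c(1, 3), 11), "variance")
  expect_true(is.na(ev$r2))
})

test_that("repeated-split cross-validation aggregates correctly", {
  st <- simulate_supervised_track(400, c(0, 1, 0), noise_sd = 0.3, seed = 1)
  ds <- make_windows(standardize_features(st$features), st$target, 1)
  cv <- cross_validate(model_spec("constant"), ds, split_spec(seed = 10),
                       n_repeats = 4)
  expect_equal(nrow(cv$repeats), 4 * 3 * 4)  # repeats x splits x metrics
  s <- cv$summary
  expect_true(all(s$sd >= 0))
  for (i in seq_len(nrow(s))) {
    vals <- cv$repeats$value[cv$repeats$split == s$split[i] &
                               cv$repeats$metric == s$metric[i]]
    expect_gte(s$mean[i], min(vals)); expect_lte(s$mean[i], max(vals))
  }
  # the constant model is deterministic: repeat-to-repeat spread comes only
  # from the resplit, and train R2 is 0 in every round
  r2 <- cv$repeats$value[cv$repeats$split == "train" & cv$repeats$metric == "r2"]
  expect_equal(r2, rep(0, 4), tolerance = 1e-12)
  expect_error(cross_validate(model_spec("constant"), ds, n_repeats = 1),
               "n_repeats")
})

test_that("cross-validated linear wMSE is consistent with a single run", {
  st <- simulate_supervised_track(1000, c(0, 1, 0), noise_sd = 0.3, seed = 2)
  ds <- make_windows(standardize_features(st$features), st$target, 1)
  alpha <- compute_alpha(ds$targets)$alpha
  cv <- cross_validate(model_spec("linear"), ds, split_spec(seed = 3),
                       n_repeats = 10, alpha = alpha)
  s <- cv$summary[cv$summary$split == "test" & cv$summary$metric == "wmse", ]
  sp <- split_windows(ds, split_spec(seed = 99))
  single <- wmse(sp$test$targets, predict(fit_linear(sp$train), sp$test), alpha)
  expect_lt(abs(single - s$mean), 2 * s$sd + 1e-9)
})

test_that("the hyperparameter scan prefers a context window on contextual data", {
  st <- simulate_supervised_track(1200, c(1, 1, 1, 1, 1), noise_sd = 0.2,
                                  seed = 4)
  fs <- standardize_features(st$features)
  scan <- scan_hyperparameters(fs, st$target, windows = c(1, 6), units = 8,
                               split = split_spec(seed = 5,
                                                  mode = "contiguous_blocks"),
                               seed = 6, max_epochs = 25, patience = 25)
  expect_equal(nrow(scan$table), 2)
  expect_gt(scan$best$window, 1)
  # determinism of the full table
  scan2 <- scan_hyperparameters(fs, st$target, windows = c(1, 6), units = 8,
                                split = split_spec(seed = 5,
                                                   mode = "contiguous_blocks"),
                                seed = 6, max_epochs = 25, patience = 25)
  expect_identical(scan$table, scan2$table)
})

## Planted-importance fixture: mark1 linearly drives the target, the others
## are pure noise; mark "dup" duplicates mark1.
importance_fixture <- function(n = 2000, seed = 1, dup = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4)
  if (dup) x <- cbind(x, x[, 1] + rnorm(n, 0, 0.01))
  nm <- c("informative", "noiseA", "noiseB", "noiseC",
          if (dup) "dup" else NULL)
  y <- pmin(pmax(2 * x[, 1] + rnorm(n, 0, 0.3) + 3, 0), 10)
  bins <- bin_table(n)
  fm <- standardize_features(feature_matrix(x, nm, bins))
  make_windows(fm, target_track(y, bins), 1)
}

test_that("use-one importance ranks the planted informative mark first", {
  ds <- importance_fixture(seed = 2)
  rep <- use_one_importance(model_spec("linear", l2 = 0.2), ds,
                            split_spec(seed = 3), seed = 3)
  expect_equal(nrow(rep$table), 4 + 2)
  expect_setequal(rep$table$mark,
                  c("all", "informative", "noiseA", "noiseB", "noiseC", "const"))
  single <- rep$table[!rep$table$mark %in% c("all", "const"), ]
  expect_equal(single$mark[which.min(single$test)], "informative")
  # a noise-only mark performs about as well as the constant baseline
  const_w <- rep$table$test[rep$table$mark == "const"]
  noise_w <- rep$table$test[rep$table$mark == "noiseA"]
  expect_lt(abs(noise_w - const_w) / const_w, 0.1)
})

test_that("drop-one importance penalizes the informative mark most, duplicates not at all", {
  ds <- importance_fixture(seed = 4, dup = TRUE)
  rep <- drop_one_importance(model_spec("linear", l2 = 0.2), ds,
                             split_spec(seed = 5), seed = 5)
  expect_equal(nrow(rep$table), 5 + 2)
  marks <- rep$table[!rep$table$mark %in% c("all", "const"), ]
  # dropping the informative mark degrades most among non-duplicated marks;
  # with a near-duplicate present, dropping either costs almost nothing,
  # so compare against the noise marks
  noise_deg <- marks$degradation[grepl("noise", marks$mark)]
  expect_lt(max(abs(noise_deg)), 0.05)
  expect_lt(abs(marks$degradation[marks$mark == "dup"]), 0.05)

  # without the duplicate, the informative mark dominates
  ds2 <- importance_fixture(seed = 6)
  rep2 <- drop_one_importance(model_spec("linear", l2 = 0.2), ds2,
                              split_spec(seed = 7), seed = 7)
  m2 <- rep2$table[!rep2$table$mark %in% c("all", "const"), ]
  expect_equal(m2$mark[which.max(m2$degradation)], "informative")
  expect_gt(max(m2$degradation), 10 * max(abs(m2$degradation[m2$mark != "informative"])))
})

test_that("use-one and drop-one agree on the top mark across seeds", {
  tops <- vapply(c(11, 12, 13), function(s) {
    ds <- importance_fixture(seed = s)
    u <- use_one_importance(model_spec("linear", l2 = 0.2), ds,
                            split_spec(seed = s), seed = s)
    d <- drop_one_importance(model_spec("linear", l2 = 0.2), ds,
                             split_spec(seed = s), seed = s)
    su <- u$table[!u$table$mark %in% c("all", "const"), ]
    sd_ <- d$table[!d$table$mark %in% c("all", "const"), ]
    su$mark[which.min(su$test)] == sd_$mark[which.max(sd_$degradation)]
  }, logical(1))
  expect_gte(sum(tops), 2)  # median agreement over 3 seeds
})

test_that("pooled training reports per-line and pooled test wMSE", {
  mk <- function(seed) {
    st <- simulate_supervised_track(400, c(0, 1, 0), noise_sd = 0.3,
                                    seed = seed)
    make_windows(standardize_features(st$features), st$target, 1)
  }
  tab <- pooled_training(model_spec("linear"),
                         list(S2 = mk(1), Kc167 = mk(2)),
                         split_spec(seed = 3), seed = 3)
  expect_equal(tab$line, c("S2", "Kc167", "all"))
  expect_true(all(is.finite(tab$test_wmse)))
})
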