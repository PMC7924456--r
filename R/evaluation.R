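## Metrics, repeated-split cross-validation, hyperparameter scans and
## use-one / drop-one feature-importance procedures.

#' Regression metrics for one split
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param alpha wMSE weighting constant (see [compute_alpha()]).
#' @return A list with `mse`, `mae`, `r2`, `wmse`, `n`. `r2` is computed
#'   against the split's own target variance and reported as `NA` (with a
#'   warning) when that variance is zero.
#' @export
evaluate_predictions <- function(y_true, y_pred, alpha) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mse <- mean((y_true - y_pred)^2)
  mae <- mean(abs(y_true - y_pred))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot < 1e-300) {
    warning("zero target variance: R^2 undefined")
    r2 <- NA_real_
  } else r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  list(mse = mse, mae = mae, r2 = r2,
       wmse = wmse(y_true, y_pred, alpha), n = length(y_true))
}

## Evaluate one fitted model on the three splits of a split_windows() result.
eval_on_splits <- function(model, splits, alpha) {
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    ds <- splits[[s]]
    evaluate_predictions(ds$targets, predict(model, ds), alpha)
  })
  structure(list(splits = out, alpha = alpha), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("split      n      MSE      MAE       R2     wMSE\n")
  for (s in names(x$splits)) {
    m <- x$splits[[s]]
    cat(sprintf("%-8s %5d %8.4f %8.4f %8.4f %8.4f\n",
                s, m$n, m$mse, m$mae, m$r2, m$wmse))
  }
  invisible(x)
}

report_row <- function(report, split, metric) report$splits[[split]][[metric]]

#' Repeated-split cross-validation
#'
#' Repeats the full protocol `n_repeats` times: a fresh seeded random
#' resplit, fresh training, evaluation on all three splits; reports the
#' mean and standard deviation of every metric.
#'
#' @param spec A [model_spec()].
#' @param ds A `windowed_dataset`.
#' @param split A [split_spec()]; its seed is the base seed, repeat `r`
#'   uses `seed + r - 1`.
#' @param n_repeats Number of rounds (default 10; must be >= 2).
#' @param alpha wMSE constant; computed from the full dataset when omitted.
#' @return A `cv_report` with `summary` (metric x split mean/sd) and the
#'   per-repeat values in `repeats`.
#' @export
cross_validate <- function(spec, ds, split = split_spec(), n_repeats = 10,
                           alpha = NULL) {
  if (n_repeats < 2) stop("n_repeats must be >= 2 for a standard deviation")
  if (is.null(alpha)) alpha <- compute_alpha(ds$targets)$alpha
  rows <- list()
  for (r in seq_len(n_repeats)) {
    sp <- split
    sp$seed <- split$seed + r - 1L
    splits <- split_windows(ds, sp)
    model <- fit_spec(spec, splits$train, splits$val, seed = sp$seed)
    rep_eval <- eval_on_splits(model, splits, alpha)
    for (s in c("train", "val", "test"))
      for (metric in c("mse", "mae", "r2", "wmse"))
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = r, split = s, metric = metric,
          value = report_row(rep_eval, s, metric))
  }
  repeats <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(repeats, repeats[c("split", "metric")]),
    function(d) data.frame(split = d$split[1], metric = d$metric[1],
                           mean = mean(d$value), sd = sd(d$value))))
  rownames(summary) <- NULL
  structure(list(summary = summary, repeats = repeats,
                 n_repeats = n_repeats, alpha = alpha, family = spec$family),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cross-validation of %s over %d repeats (alpha %.3g)\n",
              x$family, x$n_repeats, x$alpha))
  s <- x$summary[x$summary$metric == "wmse", ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s wMSE %.4f +/- %.4f\n", s$split[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Scan biLSTM window sizes and unit counts
#'
#' Retrains one biLSTM per grid cell (fixed seeds) and records train and
#' test wMSE; the argmin cell over the test wMSE is reported.
#'
#' @param fm Standardized [feature_matrix()].
#' @param tt [target_track()] on the same bins.
#' @param windows Window sizes to scan.
#' @param units Hidden-unit counts to scan (reference grid:
#'   1, 4, 8, 16, 32, 64, 128, 256, 512).
#' @param split A [split_spec()].
#' @param seed Training seed.
#' @param ... Further arguments to [fit_bilstm()] (epochs, patience, ...).
#' @return A `scan_report` with the wMSE table (`|windows| * |units|` rows)
#'   and the best cell.
#' @export
scan_hyperparameters <- function(fm, tt, windows = 1:10,
                                 units = c(1, 4, 8, 16, 32, 64, 128, 256, 512),
                                 split = split_spec(), seed = 1L, ...) {
  alpha <- compute_alpha(tt$values)$alpha
  rows <- list()
  for (t in windows) {
    ds <- make_windows(fm, tt, t)
    splits <- split_windows(ds, split)
    for (u in units) {
      model <- fit_bilstm(splits$train, splits$val, units = u,
                          alpha = alpha, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        window = t, units = u,
        train_wmse = wmse(splits$train$targets,
                          predict(model, splits$train), alpha),
        test_wmse = wmse(splits$test$targets,
                         predict(model, splits$test), alpha))
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, best = tab[which.min(tab$test_wmse), ],
                 alpha = alpha), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("biLSTM hyperparameter scan (test wMSE):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("best: window %d, %d units (test wMSE %.4f)\n",
              x$best$window, x$best$units, x$best$test_wmse))
  invisible(x)
}

importance_fit_eval <- function(spec, ds, split, seed, alpha) {
  splits <- split_windows(ds, split)
  model <- fit_spec(spec, splits$train, splits$val, seed = seed)
  vapply(c(train = "train", val = "val", test = "test"), function(s)
    wmse(splits[[s]]$targets, predict(model, splits[[s]]), alpha),
    numeric(1))
}

importance_report <- function(mode, rows, alpha) {
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(mode = mode, table = tab, alpha = alpha),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("%s feature importance (wMSE, alpha %.3g):\n",
              gsub("_", "-", x$mode), x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Use-one feature importance
#'
#' Retrains the model from scratch on every single mark alone and records
#' the wMSE per split, alongside an all-features reference and the
#' constant-baseline reference. Lower wMSE = more informative mark.
#'
#' @param spec A [model_spec()].
#' @param ds A `windowed_dataset` with at least 2 marks.
#' @param split A [split_spec()].
#' @param seed Training seed.
#' @param alpha wMSE constant; computed from the dataset when omitted.
#' @return An `importance_report` with `n_marks + 2` rows.
#' @export
use_one_importance <- function(spec, ds, split = split_spec(), seed = 1L,
                               alpha = NULL) {
  if (length(ds$mark_names) < 2) stop("need at least 2 marks")
  if (is.null(alpha)) alpha <- compute_alpha(ds$targets)$alpha
  rows <- list()
  w <- importance_fit_eval(spec, ds, split, seed, alpha)
  rows[[1]] <- data.frame(mark = "all", train = w[["train"]],
                          val = w[["val"]], test = w[["test"]])
  for (mk in ds$mark_names) {
    w <- importance_fit_eval(spec, select_marks(ds, mk), split, seed, alpha)
    rows[[length(rows) + 1L]] <- data.frame(mark = mk, train = w[["train"]],
                                            val = w[["val"]], test = w[["test"]])
  }
  w <- importance_fit_eval(model_spec("constant"), ds, split, seed, alpha)
  rows[[length(rows) + 1L]] <- data.frame(mark = "const", train = w[["train"]],
                                          val = w[["val"]], test = w[["test"]])
  importance_report("use_one", rows, alpha)
}

#' Drop-one feature importance
#'
#' One by one replaces each (standardized) mark column with zeros — zero
#' being the mark's mean signal after z-scaling — retrains on all columns
#' and records the wMSE; `degradation = wmse_dropped - wmse_all` on the
#' test split.
#'
#' @inheritParams use_one_importance
#' @return An `importance_report` with `n_marks + 2` rows and a
#'   `degradation` column.
#' @export
drop_one_importance <- function(spec, ds, split = split_spec(), seed = 1L,
                                alpha = NULL) {
  if (length(ds$mark_names) < 2) stop("need at least 2 marks")
  if (is.null(alpha)) alpha <- compute_alpha(ds$targets)$alpha
  rows <- list()
  w_all <- importance_fit_eval(spec, ds, split, seed, alpha)
  rows[[1]] <- data.frame(mark = "all", train = w_all[["train"]],
                          val = w_all[["val"]], test = w_all[["test"]],
                          degradation = 0)
  for (mk in ds$mark_names) {
    w <- importance_fit_eval(spec, zero_mark(ds, mk), split, seed, alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      mark = mk, train = w[["train"]], val = w[["val"]], test = w[["test"]],
      degradation = w[["test"]] - w_all[["test"]])
  }
  w <- importance_fit_eval(model_spec("constant"), ds, split, seed, alpha)
  rows[[length(rows) + 1L]] <- data.frame(
    mark = "const", train = w[["train"]], val = w[["val"]], test = w[["test"]],
    degradation = w[["test"]] - w_all[["test"]])
  importance_report("drop_one", rows, alpha)
}

#' Pooled multi-dataset training
#'
#' Trains one model on the union of several datasets (e.g. synthetic "cell
#' lines") and reports the test wMSE per source dataset as well as pooled.
#'
#' @param spec A [model_spec()].
#' @param ds_list Named list of `windowed_dataset`s with identical window
#'   size and marks.
#' @param split A [split_spec()] applied within each dataset.
#' @param seed Training seed.
#' @return Data frame of per-line and pooled test wMSE.
#' @export
pooled_training <- function(spec, ds_list, split = split_spec(), seed = 1L) {
  stopifnot(length(ds_list) >= 2, !is.null(names(ds_list)))
  splits <- lapply(ds_list, split_windows, spec = split)
  bind_ds <- function(dss) {
    out <- dss[[1]]
    out$windows <- do.call(abind3, lapply(dss, `[[`, "windows"))
    out$targets <- unlist(lapply(dss, `[[`, "targets"), use.names = FALSE)
    out$window_info <- do.call(rbind, lapply(dss, `[[`, "window_info"))
    out
  }
  train <- bind_ds(lapply(splits, `[[`, "train"))
  val <- bind_ds(lapply(splits, `[[`, "val"))
  alpha <- compute_alpha(train$targets)$alpha
  model <- fit_spec(spec, train, val, seed = seed)
  per_line <- vapply(names(ds_list), function(nm) {
    te <- splits[[nm]]$test
    wmse(te$targets, predict(model, te), alpha)
  }, numeric(1))
  pooled_test <- bind_ds(lapply(splits, `[[`, "test"))
  data.frame(line = c(names(ds_list), "all"),
             test_wmse = c(per_line,
                           wmse(pooled_test$targets,
                                predict(model, pooled_test), alpha)))
}

## rbind for m x t x F arrays along the first margin
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0L)),
                          d[2], d[3]),
               dimnames = list(NULL, NULL, dimnames(parts[[1]])[[3]]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
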