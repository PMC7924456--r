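## Feature preprocessing: per-mark z-scaling, fixed-length windows with
## middle-bin targets, and train/validation/test splitting.

#' Standardize a feature matrix
#'
#' Centers every mark to mean 0 and scales it to unit population variance
#' (statistics over all bins). Zero-variance marks are centred, left
#' unscaled and flagged with a warning. Refitting on already-standardized
#' data is a no-op within tolerance.
#'
#' @param fm A [feature_matrix()].
#' @param center,scale Optional previously fitted statistics to reuse
#'   (vectors named by mark), e.g. to transform new data with training-set
#'   statistics.
#' @return The standardized [feature_matrix()], with attributes `center`,
#'   `scale` and `degenerate` (marks with zero variance).
#' @export
standardize_features <- function(fm, center = NULL, scale = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  if (nrow(x) < 2L) stop("standardization needs at least 2 bins")
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    v <- colMeans(sweep(x, 2, center)^2)  # population variance
    scale <- sqrt(v)
  }
  degenerate <- scale < 1e-12
  if (any(degenerate)) {
    warning("zero-variance marks left unscaled: ",
            paste(fm$mark_names[degenerate], collapse = ", "))
    scale[degenerate] <- 1
  }
  out <- sweep(sweep(x, 2, center), 2, scale, "/")
  res <- feature_matrix(out, fm$mark_names, fm$bins)
  attr(res, "center") <- setNames(center, fm$mark_names)
  attr(res, "scale") <- setNames(scale, fm$mark_names)
  attr(res, "degenerate") <- setNames(degenerate, fm$mark_names)
  res
}

#' Build fixed-length windows with middle-bin targets
#'
#' Each window is `t` consecutive bins of one chromosome; its label is the
#' target of the bin at the middle index `floor(t / 2)` (0-based). Windows
#' never span chromosomes; edge bins that cannot centre a full window are
#' dropped (no padding).
#'
#' @param fm A [feature_matrix()].
#' @param tt A [target_track()] on the same bin grid.
#' @param t Window size in bins (`>= 1`).
#' @return A `windowed_dataset`: `windows` (`m x t x F` array), `targets`
#'   (length `m`), `middle_index` (0-based, `t %/% 2`), and `window_info`
#'   (chrom, global row index of first and middle bin per window).
#' @export
make_windows <- function(fm, tt, t) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(tt, "target_track"))
  if (t < 1) stop("window size must be >= 1")
  if (nrow(fm$values) != length(tt$values) ||
      !all(fm$bins$start == tt$bins$start & fm$bins$chrom == tt$bins$chrom))
    stop("feature matrix and target track must share the bin grid")
  mid0 <- t %/% 2L                    # 0-based middle index
  chroms <- rle(fm$bins$chrom)
  offsets <- cumsum(c(0L, head(chroms$lengths, -1L)))
  starts <- integer(0); chrom_of <- character(0)
  for (ci in seq_along(chroms$values)) {
    n_c <- chroms$lengths[ci]
    if (n_c >= t) {
      s <- offsets[ci] + seq_len(n_c - t + 1L)
      starts <- c(starts, s)
      chrom_of <- c(chrom_of, rep(chroms$values[ci], length(s)))
    }
  }
  m <- length(starts)
  if (!m) stop("empty dataset: window size exceeds every chromosome")
  F <- ncol(fm$values)
  w <- array(0, dim = c(m, t, F),
             dimnames = list(NULL, NULL, fm$mark_names))
  for (s in seq_len(t)) w[, s, ] <- fm$values[starts + s - 1L, , drop = FALSE]
  mids <- starts + mid0
  structure(list(windows = w, targets = tt$values[mids],
                 middle_index = mid0, t = as.integer(t),
                 mark_names = fm$mark_names,
                 window_info = data.frame(chrom = chrom_of, start_bin = starts,
                                          mid_bin = mids,
                                          stringsAsFactors = FALSE),
                 gamma_max = tt$gamma_max),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("windowed_dataset: %d windows of %d bins x %d marks (middle index %d)\n",
              dim(x$windows)[1], x$t, dim(x$windows)[3], x$middle_index))
  invisible(x)
}

#' @export
dim.windowed_dataset <- function(x) dim(x$windows)

## Subset a windowed dataset by window index / by mark; zero out one mark.
subset_windows <- function(ds, idx) {
  out <- ds
  out$windows <- ds$windows[idx, , , drop = FALSE]
  out$targets <- ds$targets[idx]
  out$window_info <- ds$window_info[idx, , drop = FALSE]
  out
}

select_marks <- function(ds, marks) {
  keep <- match(marks, ds$mark_names)
  if (anyNA(keep)) stop("unknown marks: ",
                        paste(marks[is.na(keep)], collapse = ", "))
  out <- ds
  out$windows <- ds$windows[, , keep, drop = FALSE]
  out$mark_names <- ds$mark_names[keep]
  out
}

zero_mark <- function(ds, mark) {
  j <- match(mark, ds$mark_names)
  if (is.na(j)) stop("unknown mark: ", mark)
  out <- ds
  out$windows[, , j] <- 0
  out
}

## Flatten a t = 1 dataset to a plain feature matrix for per-bin models.
flatten_windows <- function(ds) {
  if (ds$t != 1L)
    stop("this model family requires per-bin input (window size 1)")
  x <- matrix(ds$windows[, 1L, ], nrow = dim(ds$windows)[1],
              ncol = dim(ds$windows)[3])
  colnames(x) <- ds$mark_names
  x
}

#' Split specification
#'
#' @param train_frac,test_frac,val_frac Split fractions; must sum to 1.
#'   Defaults 0.7 / 0.2 / 0.1.
#' @param seed Integer seed for the shuffle.
#' @param mode `"random_bins"` shuffles windows before cutting;
#'   `"contiguous_blocks"` cuts the genome into consecutive runs (a
#'   leakage-safe alternative for overlapping windows).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.7, test_frac = 0.2, val_frac = 0.1,
                       seed = 1L,
                       mode = c("random_bins", "contiguous_blocks")) {
  mode <- match.arg(mode)
  if (abs(train_frac + test_frac + val_frac - 1) > 1e-9)
    stop("config error: split fractions must sum to 1")
  if (min(train_frac, test_frac, val_frac) < 0)
    stop("config error: negative split fraction")
  structure(list(train_frac = train_frac, test_frac = test_frac,
                 val_frac = val_frac, seed = as.integer(seed), mode = mode),
            class = "split_spec")
}

#' Split a windowed dataset into train / validation / test
#'
#' A disjoint, exhaustive partition of window indices. `random_bins`
#' shuffles with the spec's seed, then cuts at `floor(0.7 m)` and
#' `floor(0.9 m)` (train, test, validation in that order, for the default
#' fractions). `contiguous_blocks` assigns consecutive genome runs instead.
#'
#' @param ds A [make_windows()] result with at least 10 windows.
#' @param spec A [split_spec()].
#' @return A list with `train`, `val`, `test` windowed datasets and the
#'   index partition in `indices`.
#' @export
split_windows <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "windowed_dataset"), inherits(spec, "split_spec"))
  m <- dim(ds$windows)[1]
  if (m < 10) stop("need at least 10 windows to split")
  ord <- if (spec$mode == "random_bins") {
    set.seed(spec$seed)
    sample.int(m)
  } else seq_len(m)
  c1 <- floor(spec$train_frac * m + 1e-9)
  c2 <- floor((spec$train_frac + spec$test_frac) * m + 1e-9)
  idx <- list(train = sort(ord[seq_len(c1)]),
              test = sort(ord[seq.int(c1 + 1L, c2)]),
              val = sort(ord[seq.int(c2 + 1L, m)]))
  list(train = subset_windows(ds, idx$train),
       val = subset_windows(ds, idx$val),
       test = subset_windows(ds, idx$test),
       indices = idx)
}
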