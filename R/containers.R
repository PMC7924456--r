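## Core containers: contact maps, binned feature matrices, target tracks.
## All genomic coordinates are 0-based half-open; bin i (1-based in R) covers
## [start_bp + (i-1)*bin_size, start_bp + i*bin_size).

#' Contact map container
#'
#' A symmetric, non-negative bin-by-bin Hi-C interaction matrix together with
#' its chromosome label and bin size.
#'
#' @param matrix Square numeric matrix of contact counts; must be symmetric
#'   within `1e-8` and entrywise non-negative.
#' @param chrom Chromosome label.
#' @param bin_size_bp Bin width in base pairs.
#' @param start_bp Genomic start of bin 1 (default 0).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(matrix, chrom = "chr", bin_size_bp = 20000L,
                        start_bp = 0L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1L || nrow(matrix) != ncol(matrix))
    stop("contact map must be a square matrix with n >= 1")
  if (any(!is.finite(matrix)))
    stop("contact map contains non-finite entries")
  if (any(matrix < 0))
    stop("contact map entries must be non-negative")
  if (max(abs(matrix - t(matrix))) > 1e-8)
    stop("contact map must be symmetric (max |A - t(A)| > 1e-8)")
  if (bin_size_bp <= 0) stop("bin_size_bp must be positive")
  structure(
    list(matrix = unname(matrix), chrom = as.character(chrom),
         bin_size_bp = as.integer(bin_size_bp), start_bp = as.integer(start_bp)),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins of %d bp (start %d)\n",
              x$chrom, nrow(x$matrix), x$bin_size_bp, x$start_bp))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$matrix)

#' Bin table for a single chromosome
#'
#' @param n_bins Number of bins.
#' @param chrom Chromosome label.
#' @param bin_size_bp Bin width in base pairs.
#' @param start_bp Genomic start of the first bin.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
bin_table <- function(n_bins, chrom = "chr", bin_size_bp = 20000L,
                      start_bp = 0L) {
  starts <- start_bp + (seq_len(n_bins) - 1L) * as.integer(bin_size_bp)
  data.frame(chrom = chrom, start = starts, end = starts + bin_size_bp,
             stringsAsFactors = FALSE)
}

validate_bins <- function(bins) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  w <- bins$end - bins$start
  if (any(w <= 0)) stop("bins must have end > start")
  if (length(unique(w)) > 1L) stop("bins must share a single width")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins must be sorted and non-overlapping within each chromosome")
  }
  invisible(bins)
}

#' Feature matrix of chromatin-mark signals
#'
#' Bins-by-marks signal table with per-bin genomic coordinates. Marks are
#' chromatin features (transcription factors, insulator proteins, histone
#' modifications) binned at the contact-map resolution.
#'
#' @param values Numeric matrix, `n_bins x n_marks`.
#' @param mark_names Unique mark names, one per column.
#' @param bins Bin table as from [bin_table()].
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, mark_names, bins) {
  values <- as.matrix(values)
  if (missing(mark_names)) mark_names <- colnames(values)
  if (is.null(mark_names)) stop("mark names are required")
  mark_names <- as.character(mark_names)
  if (length(mark_names) != ncol(values))
    stop("one mark name per column required")
  if (anyDuplicated(mark_names)) stop("duplicate mark names")
  validate_bins(bins)
  if (nrow(bins) != nrow(values)) stop("bins and values disagree on n_bins")
  colnames(values) <- mark_names
  structure(list(values = values, mark_names = mark_names,
                 bins = bins[, c("chrom", "start", "end")]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d bins x %d marks (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$mark_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Per-bin target track (transitional gamma)
#'
#' Holds one real value per bin in `[0, gamma_max]`; the value is the minimal
#' segmentation resolution gamma at which the bin stops being a TAD interior,
#' capped at `gamma_max` for bins that never transition.
#'
#' @param values Numeric vector of per-bin values.
#' @param bins Bin table aligned with `values`.
#' @param gamma_max Upper cap of the track.
#' @return An object of class `target_track`.
#' @export
target_track <- function(values, bins, gamma_max = 10) {
  validate_bins(bins)
  values <- as.numeric(values)
  if (length(values) != nrow(bins)) stop("values and bins disagree on n_bins")
  if (any(values < 0 | values > gamma_max))
    stop("target values must lie in [0, gamma_max]")
  structure(list(values = values, bins = bins, gamma_max = gamma_max),
            class = "target_track")
}

#' @export
print.target_track <- function(x, ...) {
  cat(sprintf("target_track: %d bins, range [%.3g, %.3g], cap %.3g\n",
              length(x$values), min(x$values), max(x$values), x$gamma_max))
  invisible(x)
}
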