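## Readers/writers for the plain-text formats the pipeline touches.
## Everything genomic is 0-based half-open (BED/bedGraph convention).

#' Read a contact map from dense or sparse text
#'
#' Dense input is a whitespace/tab-separated numeric matrix; sparse input has
#' three columns `(bin_i, bin_j, count)` with 0-based bin indices, and is
#' symmetrized (each value assigned to both `(i,j)` and `(j,i)`). Dense input
#' with `max|A - t(A)| > 1e-6` is rejected.
#'
#' @param path Input file.
#' @param chrom Chromosome label for the map.
#' @param bin_size_bp Bin width in base pairs.
#' @param n_bins For sparse input, the matrix dimension; inferred as
#'   `max(index) + 1` when omitted.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, chrom = "chr", bin_size_bp = 20000L,
                             n_bins = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty contact-map file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop("format error: ragged rows in ", path)
  vals <- suppressWarnings(lapply(fields, as.numeric))
  if (any(vapply(vals, anyNA, logical(1))))
    stop("format error: non-numeric entries in ", path)
  m <- do.call(rbind, vals)
  sparse <- ncol(m) == 3L && nrow(m) != 3L
  if (ncol(m) == 3L && nrow(m) == 3L)  # ambiguous 3x3: treat as dense
    sparse <- FALSE
  if (sparse) {
    i <- m[, 1]; j <- m[, 2]; v <- m[, 3]
    if (any(i != floor(i)) || any(j != floor(j)) || any(i < 0) || any(j < 0))
      stop("format error: sparse bin indices must be non-negative integers")
    if (any(v < 0)) stop("value error: negative contact counts")
    n <- if (is.null(n_bins)) as.integer(max(i, j) + 1) else as.integer(n_bins)
    A <- matrix(0, n, n)
    A[cbind(i + 1, j + 1)] <- v
    A[cbind(j + 1, i + 1)] <- v
  } else {
    if (nrow(m) != ncol(m)) stop("format error: dense matrix not square")
    if (any(m < 0)) stop("value error: negative contact counts")
    if (max(abs(m - t(m))) > 1e-6)
      stop("value error: dense matrix is asymmetric (max|A - t(A)| > 1e-6)")
    A <- (m + t(m)) / 2  # remove sub-tolerance asymmetry
  }
  contact_map(A, chrom = chrom, bin_size_bp = bin_size_bp)
}

#' Write a contact map as dense TSV
#' @param map A [contact_map()].
#' @param path Output file.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  write.table(format(map$matrix, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bedgraph_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) < 4L)) stop("format error: bedGraph needs 4 columns")
  rec <- data.frame(
    chrom = vapply(f, `[`, character(1), 1L),
    start = as.numeric(vapply(f, `[`, character(1), 2L)),
    end = as.numeric(vapply(f, `[`, character(1), 3L)),
    value = as.numeric(vapply(f, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  if (any(rec$end <= rec$start))
    stop("format error: bedGraph interval with end <= start")
  rec
}

#' Read chromatin-mark bedGraph tracks onto a bin grid
#'
#' Each track is resampled to the bin grid by coverage-weighted mean over the
#' intervals overlapping each bin. Bins covered by no record get signal 0 (a
#' message reports how many).
#'
#' @param paths Named character vector or list of bedGraph files; names become
#'   mark names (basenames without extension by default).
#' @param bins Bin table as from [bin_table()].
#' @return A [feature_matrix()].
#' @export
read_mark_bedgraph <- function(paths, bins) {
  validate_bins(bins)
  paths <- unlist(paths)
  nm <- names(paths)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- sub("\\.[^.]*$", "", basename(paths))
  vals <- matrix(0, nrow(bins), length(paths))
  for (k in seq_along(paths)) {
    rec <- read_bedgraph_records(paths[[k]])
    uncovered <- 0L
    for (i in seq_len(nrow(bins))) {
      r <- rec[rec$chrom == bins$chrom[i] &
                 rec$end > bins$start[i] & rec$start < bins$end[i], ]
      if (!nrow(r)) { uncovered <- uncovered + 1L; next }
      cov <- pmin(r$end, bins$end[i]) - pmax(r$start, bins$start[i])
      vals[i, k] <- sum(r$value * cov) / sum(cov)
    }
    if (uncovered > 0L)
      message(sprintf("%s: %d of %d bins uncovered, set to 0",
                      nm[k], uncovered, nrow(bins)))
  }
  feature_matrix(vals, nm, bins)
}

#' Write a target track as bedGraph
#'
#' @param track A [target_track()].
#' @param path Output file.
#' @return The path, invisibly. Values survive a write/read round trip
#'   within 1e-9.
#' @export
write_target_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "target_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%.10g", track$bins$chrom,
                     as.integer(track$bins$start), as.integer(track$bins$end),
                     track$values), con)
  invisible(path)
}

#' Read a target track written by [write_target_bedgraph()]
#' @param path bedGraph file with one record per bin.
#' @param gamma_max Track cap.
#' @return A [target_track()].
#' @export
read_target_bedgraph <- function(path, gamma_max = 10) {
  rec <- read_bedgraph_records(path)
  target_track(rec$value,
               data.frame(chrom = rec$chrom, start = rec$start, end = rec$end,
                          stringsAsFactors = FALSE),
               gamma_max = gamma_max)
}

#' Write a segmentation as BED
#'
#' One BED line per domain, 0-based half-open; the name field carries the
#' annotation class. An empty segmentation produces an empty file.
#'
#' @param seg A `segmentation` as returned by [segment_map()].
#' @param path Output file.
#' @param chrom Chromosome label; defaults to the segmentation's.
#' @export
write_segmentation_bed <- function(seg, path, chrom = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  if (is.null(chrom)) chrom <- seg$chrom
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(seg$domains)) {
    start_bp <- seg$start_bp + (seg$domains$start - 1L) * seg$bin_size_bp
    end_bp <- seg$start_bp + seg$domains$end * seg$bin_size_bp
    writeLines(sprintf("%s\t%d\t%d\tTAD\t%d\t.", chrom,
                       as.integer(start_bp), as.integer(end_bp),
                       seq_len(nrow(seg$domains))), con)
  }
  invisible(path)
}
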