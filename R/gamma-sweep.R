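## Sweep the segmentation over a gamma grid and reduce the per-bin
## annotations to the transitional-gamma target: the minimal gamma at which
## a bin stops being a TAD interior (becomes boundary or inter-TAD). Bins
## that are TAD at every swept gamma receive the cap value gamma_max.

#' Gamma grid for the segmentation sweep
#'
#' An inclusive arithmetic sequence built by integer multiplication of the
#' step (no floating accumulation), rounded at the step's precision.
#'
#' @param start,stop Grid range (defaults 0 and 10).
#' @param step Grid step (default 0.01).
#' @return A list of class `gamma_grid` with the `values` vector.
#' @export
gamma_grid <- function(start = 0, stop = 10, step = 0.01) {
  if (step <= 0) stop("config error: step must be positive")
  if (start > stop) stop("config error: start > stop")
  k <- floor((stop - start) / step + 1e-9)
  digits <- max(0, -floor(log10(step)) + 1)
  values <- round(start + (0:k) * step, digits)
  if (values[length(values)] < stop - 1e-9)
    values <- c(values, stop)
  structure(list(start = start, stop = stop, step = step, values = values),
            class = "gamma_grid")
}

#' Sweep a contact map over a gamma grid
#'
#' Runs one segmentation per grid value (in grid order) and collects the
#' per-bin annotations. Deterministic.
#'
#' @param map A [contact_map()].
#' @param grid A [gamma_grid()].
#' @param transform Optional count transform (see [segment_map()]).
#' @return An `annotation_sweep`: `annotation` is an `n_gammas x n_bins`
#'   character matrix, plus per-gamma `objective`, `n_domains` and
#'   `mean_length` summaries.
#' @export
gamma_sweep <- function(map, grid = gamma_grid(),
                        transform = c("none", "log1p")) {
  stopifnot(inherits(map, "contact_map"))
  if (!inherits(grid, "gamma_grid") || !length(grid$values))
    stop("config error: empty or invalid gamma grid")
  cache <- score_cache(map, transform)
  res <- cpp_sweep(cache$Q0, grid$values)
  codes <- c("interTAD", "boundary", "TAD")
  ann <- matrix(codes[t(res$annotation) + 1L],
                nrow = length(grid$values), ncol = cache$n)
  structure(list(grid = grid, annotation = ann,
                 objective = as.numeric(res$objective),
                 n_domains = as.integer(res$n_domains),
                 mean_length = as.numeric(res$mean_length),
                 chrom = map$chrom, bin_size_bp = map$bin_size_bp,
                 start_bp = map$start_bp),
            class = "annotation_sweep")
}

#' @export
print.annotation_sweep <- function(x, ...) {
  cat(sprintf("annotation_sweep: %d gammas [%.3g, %.3g] x %d bins\n",
              length(x$grid$values), x$grid$start, x$grid$stop,
              ncol(x$annotation)))
  invisible(x)
}

#' Transitional gamma of every bin
#'
#' For each bin, the smallest grid gamma at which its annotation is
#' `"boundary"` or `"interTAD"` (a first-crossing minimum: bins may revert
#' to TAD at larger gamma). Bins annotated TAD at every grid gamma receive
#' `gamma_max`.
#'
#' @param sweep An [gamma_sweep()] result (rows ordered by increasing gamma).
#' @param gamma_max Cap value; defaults to the grid stop. Must not be
#'   smaller than the grid stop.
#' @return A [target_track()].
#' @export
transitional_gamma <- function(sweep, gamma_max = NULL) {
  stopifnot(inherits(sweep, "annotation_sweep"))
  if (is.null(gamma_max)) gamma_max <- sweep$grid$stop
  if (gamma_max < sweep$grid$stop)
    stop("config error: gamma_max must be >= grid stop")
  gv <- sweep$grid$values
  vals <- apply(sweep$annotation, 2, function(a) {
    i <- which(a != "TAD")[1]
    if (is.na(i)) gamma_max else gv[i]
  })
  bins <- bin_table(ncol(sweep$annotation), chrom = sweep$chrom,
                    bin_size_bp = sweep$bin_size_bp, start_bp = sweep$start_bp)
  target_track(vals, bins, gamma_max = gamma_max)
}
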