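## Synthetic planted-TAD contact maps and chromatin-mark tracks.
## The generators make every downstream stage testable without external
## Hi-C/ChIP data; they are pure functions of their config + seed.

#' Configuration for the planted-TAD contact-map simulator
#'
#' @param n_bins Number of genomic bins.
#' @param bin_size_bp Bin width in base pairs (default 20 kb, the working
#'   resolution for fly-sized genomes).
#' @param tad_length_range Integer `(min, max)` of planted TAD lengths in bins.
#'   The default 5--10 bins brackets the typical ~120 kb fly TAD at 20 kb bins.
#' @param intra_tad_enrichment Mean contact multiplier inside a TAD (> 1 for
#'   detectable TADs).
#' @param decay_exponent Power-law exponent of the distance-decay background.
#' @param noise_sd Standard deviation of the additive Gaussian noise; the
#'   noisy matrix is truncated at 0 so counts stay non-negative.
#' @param gap_fraction Fraction of bins left outside any TAD, inserted as
#'   unstructured runs between planted TADs (default 0: TADs tile the map).
#' @param seed Integer seed.
#' @return A list of class `map_sim_config`.
#' @export
map_sim_config <- function(n_bins, bin_size_bp = 20000L,
                           tad_length_range = c(5L, 10L),
                           intra_tad_enrichment = 4,
                           decay_exponent = 0.8,
                           noise_sd = 0.5,
                           gap_fraction = 0,
                           seed = 1L) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1)
    stop("invalid config: n_bins must be a positive integer")
  tad_length_range <- as.integer(tad_length_range)
  if (length(tad_length_range) != 2L || tad_length_range[1] < 2L)
    stop("invalid config: tad_length_range min must be >= 2")
  if (tad_length_range[2] > n_bins)
    stop("invalid config: tad_length_range max must be <= n_bins")
  if (tad_length_range[1] > tad_length_range[2])
    stop("invalid config: tad_length_range min > max")
  if (intra_tad_enrichment <= 0) stop("invalid config: enrichment must be positive")
  if (decay_exponent <= 0) stop("invalid config: decay_exponent must be positive")
  if (noise_sd < 0) stop("invalid config: noise_sd must be non-negative")
  if (gap_fraction < 0 || gap_fraction >= 1) stop("invalid config: gap_fraction in [0,1)")
  structure(list(n_bins = as.integer(n_bins), bin_size_bp = as.integer(bin_size_bp),
                 tad_length_range = tad_length_range,
                 intra_tad_enrichment = intra_tad_enrichment,
                 decay_exponent = decay_exponent, noise_sd = noise_sd,
                 gap_fraction = gap_fraction, seed = as.integer(seed)),
            class = "map_sim_config")
}

## Tile [1, n_bins] with TADs of random lengths, optionally interleaving
## unstructured gap bins. Returns a data frame (start, end) of planted TADs.
plant_tads <- function(cfg) {
  n <- cfg$n_bins
  lo <- cfg$tad_length_range[1]; hi <- cfg$tad_length_range[2]
  n_gap <- floor(cfg$gap_fraction * n)
  tads <- list(); pos <- 1L; budget <- n - n_gap
  used <- 0L
  while (used + lo <= budget) {
    len <- sample(seq.int(lo, hi), 1L)
    len <- min(len, budget - used)
    if (len < lo) break
    tads[[length(tads) + 1L]] <- c(used + 1L, used + len)
    used <- used + len
  }
  tads <- do.call(rbind, tads)
  # distribute gap bins (plus any tiling remainder) between TADs and at ends
  slack <- n - used
  k <- nrow(tads)
  if (slack > 0L) {
    cuts <- sort(sample.int(k + 1L, slack, replace = TRUE))  # gap slot per spare bin
    gaps <- tabulate(cuts, nbins = k + 1L)
    shift <- cumsum(c(gaps[seq_len(k)]))
    tads[, 1] <- tads[, 1] + shift
    tads[, 2] <- tads[, 2] + shift
  }
  data.frame(start = tads[, 1], end = tads[, 2])
}

#' Simulate a contact map with planted TADs
#'
#' Mean contact between bins i and j is
#' `(1 + |i - j|)^(-decay_exponent)`, multiplied by `intra_tad_enrichment`
#' when both bins fall inside the same planted TAD, plus additive Gaussian
#' noise truncated at 0.
#'
#' @param cfg A [map_sim_config()].
#' @return A list with elements `map` (a [contact_map()]), `tads` (data frame
#'   of planted TAD `(start, end)` bins, 1-based inclusive) and
#'   `true_boundaries` (integer bin indices of planted first/last TAD bins).
#' @export
simulate_contact_map <- function(cfg) {
  stopifnot(inherits(cfg, "map_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_bins
  tads <- plant_tads(cfg)
  tad_id <- rep(NA_integer_, n)
  for (i in seq_len(nrow(tads))) tad_id[tads$start[i]:tads$end[i]] <- i
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  same <- outer(tad_id, tad_id, function(a, b) !is.na(a) & !is.na(b) & a == b)
  mu <- (1 + d)^(-cfg$decay_exponent) *
    ifelse(same, cfg$intra_tad_enrichment, 1)
  if (cfg$noise_sd > 0) {
    noise <- matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    mu <- pmax(mu + noise, 0)
  }
  boundaries <- sort(unique(c(tads$start, tads$end)))
  list(map = contact_map(mu, chrom = "chrS", bin_size_bp = cfg$bin_size_bp),
       tads = tads, true_boundaries = boundaries)
}

#' Configuration for one simulated chromatin-mark track
#'
#' @param mark_name Unique track name.
#' @param coupling One of `"boundary_enriched"` (signal peaks at TAD
#'   boundaries, like the insulator-associated Chriz factor),
#'   `"intra_tad_enriched"` (signal on TAD-interior bins, like broad
#'   repressive histone marks) or `"noise"` (no coupling).
#' @param effect_size Signal height on the coupled bins; must be 0 for
#'   `"noise"` marks.
#' @param smoothing_bins Width of the moving-average smoother applied to the
#'   coupled indicator signal (0 = none).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @return A list of class `mark_sim_config`.
#' @export
mark_sim_config <- function(mark_name,
                            coupling = c("boundary_enriched",
                                         "intra_tad_enriched", "noise"),
                            effect_size = 1, smoothing_bins = 0L,
                            noise_sd = 1) {
  coupling <- match.arg(coupling)
  if (coupling == "noise" && effect_size != 0)
    stop("noise marks must have effect_size = 0")
  if (smoothing_bins < 0) stop("smoothing_bins must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(mark_name = as.character(mark_name), coupling = coupling,
                 effect_size = effect_size,
                 smoothing_bins = as.integer(smoothing_bins),
                 noise_sd = noise_sd),
            class = "mark_sim_config")
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  kern <- rep(1 / width, width)
  out <- as.numeric(stats::filter(x, kern, sides = 2, circular = FALSE))
  # edges: renormalized partial means instead of NA
  n <- length(x); half <- (width - 1L) %/% 2L
  for (i in which(is.na(out))) {
    lo <- max(1L, i - half); hi <- min(n, i + width - 1L - half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Simulate chromatin-mark tracks coupled to planted TAD structure
#'
#' @param true_boundaries Integer bin indices of TAD boundaries.
#' @param n_bins Number of bins.
#' @param configs List of [mark_sim_config()] objects; output column order
#'   follows this list.
#' @param seed Integer seed.
#' @param tads Optional data frame `(start, end)` of planted TADs; required
#'   when any config uses `intra_tad_enriched` coupling.
#' @param bins Optional bin table; defaults to 20-kb bins on one chromosome.
#' @return A [feature_matrix()].
#' @export
simulate_mark_tracks <- function(true_boundaries, n_bins, configs, seed = 1L,
                                 tads = NULL, bins = NULL) {
  if (length(true_boundaries) &&
      (min(true_boundaries) < 1L || max(true_boundaries) > n_bins))
    stop("boundaries must lie within [1, n_bins]")
  nm <- vapply(configs, function(cf) cf$mark_name, character(1))
  if (anyDuplicated(nm)) stop("duplicate mark names")
  set.seed(seed)
  interior <- rep(FALSE, n_bins)
  if (!is.null(tads)) {
    for (i in seq_len(nrow(tads))) {
      s <- tads$start[i]; e <- tads$end[i]
      if (e - s >= 2L) interior[(s + 1L):(e - 1L)] <- TRUE
    }
  }
  vals <- vapply(configs, function(cf) {
    base <- numeric(n_bins)
    if (cf$coupling == "boundary_enriched") {
      base[true_boundaries] <- cf$effect_size
    } else if (cf$coupling == "intra_tad_enriched") {
      if (is.null(tads)) stop("intra_tad_enriched marks require the planted TAD table")
      base[interior] <- cf$effect_size
    }
    if (cf$smoothing_bins > 1L) base <- moving_average(base, cf$smoothing_bins)
    base + rnorm(n_bins, 0, cf$noise_sd)
  }, numeric(n_bins))
  if (is.null(bins)) bins <- bin_table(n_bins, chrom = "chrS")
  feature_matrix(vals, nm, bins)
}

#' Simulate a supervised feature/target pair with a planted context window
#'
#' Features are i.i.d. standard-Gaussian columns; the target at bin i is the
#' window-weighted sum of the first feature over neighbouring bins (zero
#' padded at the edges for generation), plus noise, clipped to `[0, 10]`.
#' Used to test that models exploiting genomic context beat per-bin models.
#'
#' @param n_bins Number of bins.
#' @param window_weights Odd-length numeric vector of context weights,
#'   centred on the target bin.
#' @param noise_sd Standard deviation of the target noise.
#' @param seed Integer seed.
#' @param n_marks Number of feature columns (the first carries the signal).
#' @param offset Constant added to the weighted sum before clipping
#'   (default 0); a mid-range offset keeps the clip inactive so the planted
#'   linear weights stay identifiable.
#' @param clip Target range, default `c(0, 10)` matching the transitional
#'   gamma range.
#' @return A list with `features` (a [feature_matrix()]) and `target`
#'   (a [target_track()]).
#' @export
simulate_supervised_track <- function(n_bins, window_weights, noise_sd = 0,
                                      seed = 1L, n_marks = 1L, offset = 0,
                                      clip = c(0, 10)) {
  k <- length(window_weights)
  if (k %% 2L == 0L) stop("window_weights must have odd length")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  x <- matrix(rnorm(n_bins * n_marks), n_bins, n_marks)
  half <- (k - 1L) %/% 2L
  padded <- c(numeric(half), x[, 1], numeric(half))
  y <- offset + vapply(seq_len(n_bins), function(i)
    sum(window_weights * padded[i:(i + k - 1L)]), numeric(1))
  if (noise_sd > 0) y <- y + rnorm(n_bins, 0, noise_sd)
  y <- pmin(pmax(y, clip[1]), clip[2])
  bins <- bin_table(n_bins, chrom = "chrS")
  list(features = feature_matrix(x, paste0("mark", seq_len(n_marks)), bins),
       target = target_track(y, bins, gamma_max = clip[2]))
}
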