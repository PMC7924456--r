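## Dynamic-programming TAD segmentation of a contact map at a fixed
## resolution parameter gamma, in the style of the Armatus caller.
##
## For an interval of bins [k, l] with d = l - k + 1 the raw score is
##   s_gamma(k, l) = (sum over k <= i <= j <= l of A[i, j]) / d^gamma
## (upper triangle including the diagonal), and the normalized quality is
##   q_gamma(k, l) = s_gamma(k, l) - mu_gamma(d),
## where mu_gamma(d) is the mean of s_gamma over all length-d intervals of
## the chromosome. The segmentation maximizes the sum of max(q, 0) over a
## set of disjoint intervals; only intervals with q > 0 become domains.
## Larger gamma penalizes long intervals, so mean domain size shrinks.

## Precomputed interval machinery shared across gammas.
score_cache <- function(map, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  A <- map$matrix
  if (transform == "log1p") A <- log1p(A)
  S <- cpp_interval_sums(A)
  list(S = S, Q0 = cpp_centered_scores(S), n = nrow(A))
}

#' Interval score of a candidate domain
#'
#' Returns the raw scaled intra-domain contact sum and its length-matched
#' normalization for the interval of bins `[k, l]` (1-based, inclusive).
#'
#' @param map A [contact_map()].
#' @param k,l First and last bin of the interval, `1 <= k <= l <= n`.
#' @param gamma Resolution parameter (non-negative).
#' @param cache Optional precomputed [score_cache] (internal reuse).
#' @return A list with elements `raw` (s) and `normalized` (q).
#' @export
domain_score <- function(map, k, l, gamma, cache = NULL) {
  if (is.null(cache)) cache <- score_cache(map)
  n <- cache$n
  if (k > l) stop("index error: k > l")
  if (k < 1 || l > n) stop("index error: interval outside the map")
  d <- l - k + 1
  list(raw = cache$S[k, l] / d^gamma,
       normalized = cache$Q0[k, l] / d^gamma)
}

make_segmentation <- function(domains, n, gamma, objective, map) {
  if (is.null(domains) || !nrow(domains)) {
    dom <- data.frame(start = integer(), end = integer())
  } else {
    dom <- data.frame(start = as.integer(domains[, 1]),
                      end = as.integer(domains[, 2]))
  }
  structure(list(gamma = gamma, domains = dom,
                 annotations = annotate_bins(dom, n),
                 objective = objective, n_bins = n,
                 chrom = map$chrom, bin_size_bp = map$bin_size_bp,
                 start_bp = map$start_bp),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation at gamma = %.4g: %d domains over %d bins (objective %.4g)\n",
              x$gamma, nrow(x$domains), x$n_bins, x$objective))
  invisible(x)
}

#' Segment a contact map at a fixed gamma
#'
#' Maximizes the summed normalized quality of disjoint domains by the prefix
#' dynamic program `OPT(l) = max(OPT(l-1), max_k [OPT(k-1) + q(k,l)^+])`.
#' On exact ties "no new domain" is preferred, then the smaller `k`.
#'
#' @param map A [contact_map()].
#' @param gamma Resolution parameter; larger values favour smaller domains.
#' @param transform Optional count transform applied before scoring.
#' @return A `segmentation`: domains (1-based inclusive bin intervals),
#'   per-bin annotations (`"TAD"`, `"boundary"`, `"interTAD"`) and the DP
#'   objective.
#' @export
segment_map <- function(map, gamma, transform = c("none", "log1p")) {
  stopifnot(inherits(map, "contact_map"), gamma >= 0)
  cache <- score_cache(map, transform)
  res <- cpp_segment(cache$Q0, gamma)
  make_segmentation(res$domains, cache$n, gamma, res$objective, map)
}

#' Brute-force segmentation oracle
#'
#' Exhaustively enumerates every set of disjoint intervals and returns the
#' argmax of the same objective as [segment_map()]. Exponential; refuses
#' `n > 14`. Intended for tests only.
#'
#' @inheritParams segment_map
#' @return A `segmentation`.
#' @export
segment_bruteforce <- function(map, gamma, transform = c("none", "log1p")) {
  stopifnot(inherits(map, "contact_map"))
  cache <- score_cache(map, transform)
  n <- cache$n
  if (n > 14) stop("brute-force enumeration refused for n > 14")
  q <- cache$Q0
  d <- outer(seq_len(n), seq_len(n), function(k, l) l - k + 1)
  q <- q / d^gamma
  # only positive-quality intervals can contribute to the objective, so
  # exhaustively enumerate every disjoint subset of those
  pos <- which(upper.tri(q, diag = TRUE) & q > 0, arr.ind = TRUE)
  cand <- data.frame(k = pos[, 1], l = pos[, 2],
                     q = q[pos])
  cand <- cand[order(cand$k, cand$l), ]
  N <- nrow(cand)
  best <- list(obj = 0, doms = list())
  recurse <- function(i, minstart, obj, doms) {
    if (obj > best$obj + 1e-12) best <<- list(obj = obj, doms = doms)
    if (i > N) return()
    for (j in i:N) {
      if (cand$k[j] >= minstart)
        recurse(j + 1L, cand$l[j] + 1L, obj + cand$q[j],
                c(doms, list(c(cand$k[j], cand$l[j]))))
    }
  }
  if (N > 0) recurse(1L, 1L, 0, list())
  doms <- if (length(best$doms)) do.call(rbind, best$doms) else NULL
  if (!is.null(doms)) doms <- doms[order(doms[, 1]), , drop = FALSE]
  make_segmentation(doms, n, gamma, best$obj, map)
}

#' Annotate bins from a set of domains
#'
#' First and last bin of each domain are `"boundary"`, interior bins are
#' `"TAD"`, bins outside every domain are `"interTAD"`. A length-1 domain
#' contributes a single boundary bin; a length-2 domain two boundary bins.
#'
#' @param domains Data frame (or 2-column matrix) of `(start, end)` bin
#'   intervals, 1-based inclusive, non-overlapping.
#' @param n_bins Total number of bins.
#' @return Character vector of length `n_bins`.
#' @export
annotate_bins <- function(domains, n_bins) {
  if (is.matrix(domains))
    domains <- data.frame(start = domains[, 1], end = domains[, 2])
  ann <- rep("interTAD", n_bins)
  if (!nrow(domains)) return(ann)
  o <- order(domains$start)
  domains <- domains[o, , drop = FALSE]
  if (any(domains$end < domains$start) ||
      any(domains$start < 1) || any(domains$end > n_bins))
    stop("invalid domains")
  if (nrow(domains) > 1 &&
      any(domains$start[-1] <= domains$end[-nrow(domains)]))
    stop("overlapping domains violate the segmentation invariant")
  for (i in seq_len(nrow(domains))) {
    s <- domains$start[i]; e <- domains$end[i]
    if (e - s >= 2) ann[(s + 1):(e - 1)] <- "TAD"
    ann[c(s, e)] <- "boundary"
  }
  ann
}
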