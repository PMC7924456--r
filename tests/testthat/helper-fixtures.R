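## Shared fixture builders; everything is generated in code.

random_symmetric_map <- function(n, seed, scale = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0, scale), n, n)
  contact_map((A + t(A)) / 2)
}

## Block-diagonal map: strong square blocks on a weak background.
block_map <- function(n, blocks, strong = 5, weak = 0.1) {
  A <- matrix(weak, n, n)
  for (b in blocks) A[b[1]:b[2], b[1]:b[2]] <- strong
  contact_map(A)
}

## Hand-rolled interval score oracle: direct upper-triangle enumeration.
score_oracle <- function(A, k, l, gamma) {
  s <- 0
  for (i in k:l) for (j in i:l) s <- s + A[i, j]
  s / (l - k + 1)^gamma
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
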