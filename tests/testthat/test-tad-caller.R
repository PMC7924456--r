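test_that("interval scores match direct upper-triangle enumeration", {
  # all-zero map: s = q = 0 everywhere
  z <- contact_map(matrix(0, 5, 5))
  for (kl in list(c(1, 1), c(2, 4), c(1, 5))) {
    sc <- domain_score(z, kl[1], kl[2], 1)
    expect_equal(sc$raw, 0)
    expect_equal(sc$normalized, 0)
  }
  # unit-length interval at gamma 0 is the diagonal entry
  m <- random_symmetric_map(6, seed = 1)
  for (i in 1:6)
    expect_equal(domain_score(m, i, i, 0)$raw, m$matrix[i, i])
  # 4x4 map with ones in the first 2x2 block, gamma 1: s(1,2) = 3/2
  A <- matrix(0, 4, 4); A[1:2, 1:2] <- 1
  expect_equal(domain_score(contact_map(A), 1, 2, 1)$raw, 1.5)
  # random intervals against the enumeration oracle
  m <- random_symmetric_map(9, seed = 42)
  for (case in list(c(1, 9, 0.5), c(3, 7, 2), c(2, 2, 1.3))) {
    expect_equal(domain_score(m, case[1], case[2], case[3])$raw,
                 score_oracle(m$matrix, case[1], case[2], case[3]))
  }
  expect_error(domain_score(m, 5, 3, 1), "index")
})

test_that("the DP objective equals brute-force enumeration on random maps", {
  for (seed in 1:50) {
    n <- sample(4:12, 1)
    m <- random_symmetric_map(n, seed = seed)
    for (g in c(0, 0.5, 1, 2)) {
      dp <- segment_map(m, g)
      bf <- segment_bruteforce(m, g)
      expect_equal(dp$objective, bf$objective, tolerance = 1e-10)
    }
  }
})

test_that("degenerate maps segment sensibly", {
  z <- contact_map(matrix(0, 5, 5))
  seg <- segment_map(z, 0.7)
  expect_equal(nrow(seg$domains), 0)
  expect_true(all(seg$annotations == "interTAD"))
  expect_equal(seg$objective, 0)

  one <- contact_map(matrix(0, 1, 1))
  bf <- segment_bruteforce(one, 1)
  expect_equal(bf$objective, 0)
  expect_equal(nrow(bf$domains), 0)

  # strongly scaled long domains die at large gamma on a uniform map
  ones <- contact_map(matrix(1, 3, 3))
  seg <- segment_map(ones, 10)
  expect_true(all(seg$domains$end - seg$domains$start <= 1))

  expect_error(segment_bruteforce(random_symmetric_map(15, 1), 1), "n > 14")
})

test_that("two strong disjoint blocks are recovered as two domains", {
  m <- block_map(12, list(c(2, 5), c(8, 11)))
  seg <- segment_map(m, 0.3)
  expect_equal(nrow(seg$domains), 2)
  expect_equal(seg$domains$start, c(2L, 8L))
  expect_equal(seg$domains$end, c(5L, 11L))
  bf <- segment_bruteforce(m, 0.3)
  expect_equal(seg$objective, bf$objective)
})

test_that("bin annotation follows the boundary/TAD/interTAD trichotomy", {
  ann <- annotate_bins(data.frame(start = 3, end = 6), 8)
  expect_equal(ann, c("interTAD", "interTAD", "boundary", "TAD", "TAD",
                      "boundary", "interTAD", "interTAD"))
  expect_true(all(annotate_bins(data.frame(start = integer(),
                                           end = integer()), 5) == "interTAD"))
  # degenerate domains: length 1 is a lone boundary, length 2 two boundaries
  expect_equal(annotate_bins(data.frame(start = 1, end = 1), 2),
               c("boundary", "interTAD"))
  expect_equal(annotate_bins(data.frame(start = 2, end = 3), 4),
               c("interTAD", "boundary", "boundary", "interTAD"))
  expect_error(annotate_bins(data.frame(start = c(1, 3), end = c(4, 6)), 8),
               "overlap")
  # partition: the three classes always sum to n_bins
  seg <- segment_map(random_symmetric_map(10, 3), 0.5)
  expect_equal(sum(table(factor(seg$annotations,
                                c("TAD", "boundary", "interTAD")))), 10)
})

test_that("adding a constant to the map leaves normalized scores unchanged", {
  m <- random_symmetric_map(8, seed = 5)
  shifted <- contact_map(m$matrix + 3)
  for (kl in list(c(1, 4), c(3, 8), c(5, 5))) {
    q1 <- domain_score(m, kl[1], kl[2], 0.7)$normalized
    q2 <- domain_score(shifted, kl[1], kl[2], 0.7)$normalized
    expect_equal(q1, q2, tolerance = 1e-9)
  }
})

test_that("mean called domain size shrinks as gamma grows on planted maps", {
  sim <- simulate_contact_map(map_sim_config(
    n_bins = 120, intra_tad_enrichment = 6, noise_sd = 0.3, seed = 13))
  sw <- gamma_sweep(sim$map, gamma_grid(0, 10, 0.25))
  ml <- sw$mean_length
  ml <- ml[!is.na(ml)]
  expect_true(all(diff(ml) <= 1 + 1e-9))  # non-increasing within 1 bin
  expect_gt(ml[1], tail(ml, 1))
})

test_that("the caller recovers planted boundaries at moderate gamma", {
  for (seed in c(2, 5, 9)) {
    sim <- simulate_contact_map(map_sim_config(
      n_bins = 100, intra_tad_enrichment = 6, noise_sd = 0.1, seed = seed))
    seg <- segment_map(sim$map, 0.5)
    called <- sort(unique(c(seg$domains$start, seg$domains$end)))
    hit <- vapply(sim$true_boundaries,
                  function(b) any(abs(called - b) <= 1), logical(1))
    expect_gte(mean(hit), 0.8)
  }
})

test_that("log1p transform is accepted and changes raw scores monotonically", {
  m <- random_symmetric_map(8, seed = 2, scale = 5)
  seg <- segment_map(m, 0.5, transform = "log1p")
  expect_s3_class(seg, "segmentation")
  expect_equal(domain_score(contact_map(log1p(m$matrix)), 2, 4, 0.5)$raw,
               score_oracle(log1p(m$matrix), 2, 4, 0.5))
})
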