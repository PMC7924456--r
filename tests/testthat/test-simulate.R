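test_that("simulated contact maps are symmetric, non-negative and deterministic", {
  for (seed in c(3, 7, 21)) {
    cfg <- map_sim_config(n_bins = 40, tad_length_range = c(5, 10),
                          intra_tad_enrichment = 4, seed = seed)
    sim <- simulate_contact_map(cfg)
    A <- sim$map$matrix
    expect_identical(A, t(A))
    expect_true(all(A >= 0))
    # identical rerun under the same config
    sim2 <- simulate_contact_map(cfg)
    expect_identical(A, sim2$map$matrix)
    # planted TADs tile the chromosome; boundaries are first/last TAD bins
    expect_true(all(diff(c(t(as.matrix(sim$tads[, c("start", "end")])))) >= 0))
    expect_true(all(sim$true_boundaries %in%
                      c(sim$tads$start, sim$tads$end)))
  }
})

test_that("enrichment = 1 with no noise reduces to the pure distance-decay background", {
  sim <- simulate_contact_map(map_sim_config(
    n_bins = 30, intra_tad_enrichment = 1, noise_sd = 0, seed = 5,
    decay_exponent = 0.8))
  d <- abs(outer(1:30, 1:30, "-"))
  expect_equal(sim$map$matrix, (1 + d)^(-0.8))
})

test_that("within-TAD contacts exceed between-TAD contacts at equal distance", {
  sim <- simulate_contact_map(map_sim_config(
    n_bins = 60, intra_tad_enrichment = 6, noise_sd = 0.1, seed = 11))
  A <- sim$map$matrix
  tad_id <- rep(NA_integer_, 60)
  for (i in seq_len(nrow(sim$tads)))
    tad_id[sim$tads$start[i]:sim$tads$end[i]] <- i
  for (dist in 1:3) {
    within <- between <- c()
    for (i in 1:(60 - dist)) {
      j <- i + dist
      if (!is.na(tad_id[i]) && !is.na(tad_id[j]) && tad_id[i] == tad_id[j])
        within <- c(within, A[i, j])
      else between <- c(between, A[i, j])
    }
    expect_gt(mean(within), mean(between))
  }
})

test_that("invalid map configs are rejected", {
  expect_error(map_sim_config(n_bins = 0), "n_bins")
  expect_error(map_sim_config(n_bins = 10, tad_length_range = c(1, 5)), "min")
  expect_error(map_sim_config(n_bins = 10, tad_length_range = c(5, 20)), "max")
  expect_error(map_sim_config(n_bins = 10, noise_sd = -1), "noise_sd")
})

test_that("gap fraction inserts unstructured bins between planted TADs", {
  sim <- simulate_contact_map(map_sim_config(
    n_bins = 80, gap_fraction = 0.2, seed = 9))
  in_tad <- rep(FALSE, 80)
  for (i in seq_len(nrow(sim$tads)))
    in_tad[sim$tads$start[i]:sim$tads$end[i]] <- TRUE
  expect_gt(sum(!in_tad), 0)
  expect_lte(sum(!in_tad), 0.2 * 80 + 5)  # gap bins + tiling remainder
})

test_that("mark tracks follow their coupling and are deterministic", {
  sim <- simulate_contact_map(map_sim_config(n_bins = 100, seed = 4))
  cfgs <- list(
    mark_sim_config("bdry", "boundary_enriched", effect_size = 3,
                    noise_sd = 0.1),
    mark_sim_config("intra", "intra_tad_enriched", effect_size = 2,
                    noise_sd = 0.1),
    mark_sim_config("nz", "noise", effect_size = 0, noise_sd = 1))
  fm <- simulate_mark_tracks(sim$true_boundaries, 100, cfgs, seed = 2,
                             tads = sim$tads)
  expect_identical(fm$mark_names, c("bdry", "intra", "nz"))
  b <- sim$true_boundaries
  expect_gt(mean(fm$values[b, "bdry"]), mean(fm$values[-b, "bdry"]))
  interior <- setdiff(which(!is.na(rep(1, 100))), b)  # non-boundary bins
  expect_gt(mean(fm$values[interior, "intra"]), mean(fm$values[b, "intra"]))
  fm2 <- simulate_mark_tracks(sim$true_boundaries, 100, cfgs, seed = 2,
                              tads = sim$tads)
  expect_identical(fm$values, fm2$values)
})

test_that("a pure-noise mark has mean near zero and noise marks need effect 0", {
  fm <- simulate_mark_tracks(integer(0), 1000,
                             list(mark_sim_config("nz", "noise",
                                                  effect_size = 0,
                                                  noise_sd = 1)),
                             seed = 8)
  expect_lt(abs(mean(fm$values[, 1])), 5 / sqrt(1000))
  expect_error(mark_sim_config("bad", "noise", effect_size = 1), "effect_size")
  expect_error(
    simulate_mark_tracks(1:2, 10,
                         list(mark_sim_config("a", "noise", 0),
                              mark_sim_config("a", "noise", 0))),
    "duplicate")
})

test_that("supervised track reproduces its planted window rule", {
  # identity window: target equals clipped central feature
  st <- simulate_supervised_track(200, c(0, 1, 0), noise_sd = 0, seed = 3)
  expect_equal(st$target$values, pmin(pmax(st$features$values[, 1], 0), 10))
  # 3-bin sum window, recomputed directly
  st <- simulate_supervised_track(200, c(1, 1, 1), noise_sd = 0, seed = 3)
  x <- st$features$values[, 1]
  manual <- pmin(pmax(c(0, head(x, -1)) + x + c(tail(x, -1), 0), 0), 10)
  expect_equal(st$target$values, manual)
  # zero weights give all-zero targets
  st0 <- simulate_supervised_track(50, c(0, 0, 0), noise_sd = 0, seed = 3)
  expect_true(all(st0$target$values == 0))
  expect_error(simulate_supervised_track(50, c(1, 1)), "odd")
})
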