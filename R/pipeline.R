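## End-to-end orchestration: simulate (or load) -> transitional gamma ->
## features -> train -> evaluate, from a single config, with a manifest
## recording everything needed to reproduce the run.

#' Default pipeline configuration
#'
#' Returns the demo configuration: a simulated two-chromosome genome with
#' five marks (one boundary-coupled, one TAD-interior-coupled, three noise),
#' a coarse gamma grid, and a small model set. Any field can be overridden
#' via `...` (or by loading a YAML file with [read_pipeline_config()]).
#'
#' @param ... Named overrides merged over the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulation = list(
      chromosomes = c("chr2L", "chr2R"),
      n_bins = 120L,
      intra_tad_enrichment = 6,
      decay_exponent = 0.8,
      noise_sd = 0.5,
      tad_length_range = c(5L, 10L),
      marks = list(
        list(name = "chriz_like", coupling = "boundary_enriched",
             effect_size = 3, smoothing_bins = 3L, noise_sd = 0.5),
        list(name = "repressive_like", coupling = "intra_tad_enriched",
             effect_size = 2, smoothing_bins = 3L, noise_sd = 0.5),
        list(name = "noise1", coupling = "noise", effect_size = 0,
             smoothing_bins = 0L, noise_sd = 1),
        list(name = "noise2", coupling = "noise", effect_size = 0,
             smoothing_bins = 0L, noise_sd = 1),
        list(name = "noise3", coupling = "noise", effect_size = 0,
             smoothing_bins = 0L, noise_sd = 1))),
    paths = NULL,  # alternatively: list(maps =, marks =) input files
    gamma = list(start = 0, stop = 10, step = 0.1),
    feature_set = NULL,  # NULL = all marks
    window_size = 5L,
    split = list(train = 0.7, test = 0.2, val = 0.1, mode = "random_bins"),
    models = list(
      list(family = "constant"),
      list(family = "linear", l1 = 0.2, l2 = 0.2),
      list(family = "bilstm", units = 16, max_epochs = 20, patience = 5)),
    out_dir = NULL)
  over <- list(...)
  modifyList(cfg, over)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_pipeline_config <- function(cfg) {
  has_sim <- !is.null(cfg$simulation)
  has_paths <- !is.null(cfg$paths)
  if (has_sim == has_paths)
    stop("config error: exactly one of simulation/paths must be present")
  if (has_sim && !is.null(cfg$feature_set)) {
    marks <- vapply(cfg$simulation$marks, `[[`, "", "name")
    missing <- setdiff(cfg$feature_set, marks)
    if (length(missing))
      stop("config error: feature set references unknown marks: ",
           paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

## Derive per-stage seeds from the global seed so stages can be rerun
## standalone: stage k uses seed * 101 + k (kept within 32-bit range).
stage_seed <- function(seed, k) as.integer((seed %% 20000000L) * 101L + k)

#' Run the full pipeline
#'
#' Stages: simulate (or load) contact maps and mark tracks per chromosome;
#' gamma-sweep each map and compute transitional gamma; standardize marks;
#' window and split; train every configured model; evaluate. Writes
#' `gamma.bedgraph`, per-model metric tables (TSV + JSON) and a manifest;
#' byte-identical outputs given identical config + seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (overrides `cfg$out_dir`); created if
#'   needed.
#' @return The output directory, invisibly; the collected results as the
#'   attribute `"results"`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = cfg$out_dir) {
  validate_pipeline_config(cfg)
  if (is.null(out_dir)) stop("config error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  ## stage 1: per-chromosome contact maps + mark tracks
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    chrom_data <- lapply(seq_along(sim$chromosomes), function(ci) {
      mcfg <- map_sim_config(
        n_bins = sim$n_bins,
        tad_length_range = sim$tad_length_range,
        intra_tad_enrichment = sim$intra_tad_enrichment,
        decay_exponent = sim$decay_exponent,
        noise_sd = sim$noise_sd,
        seed = stage_seed(seed, ci))
      smap <- simulate_contact_map(mcfg)
      smap$map$chrom <- sim$chromosomes[ci]
      marks <- lapply(sim$marks, function(mk)
        mark_sim_config(mk$name, mk$coupling, mk$effect_size,
                        mk$smoothing_bins, mk$noise_sd))
      fm <- simulate_mark_tracks(smap$true_boundaries, sim$n_bins, marks,
                                 seed = stage_seed(seed, 100L + ci),
                                 tads = smap$tads,
                                 bins = bin_table(sim$n_bins,
                                                  chrom = sim$chromosomes[ci]))
      list(map = smap$map, features = fm)
    })
  } else {
    chrom_data <- lapply(seq_along(cfg$paths$maps), function(ci) {
      map <- read_contact_map(cfg$paths$maps[[ci]],
                              chrom = names(cfg$paths$maps)[ci])
      bins <- bin_table(nrow(map$matrix), chrom = map$chrom,
                        bin_size_bp = map$bin_size_bp)
      list(map = map, features = read_mark_bedgraph(cfg$paths$marks, bins))
    })
  }

  ## stage 2: transitional gamma per chromosome, concatenated in order
  grid <- gamma_grid(cfg$gamma$start, cfg$gamma$stop, cfg$gamma$step)
  tracks <- lapply(chrom_data, function(cd)
    transitional_gamma(gamma_sweep(cd$map, grid)))
  bins <- do.call(rbind, lapply(tracks, `[[`, "bins"))
  tt <- target_track(unlist(lapply(tracks, `[[`, "values")), bins,
                     gamma_max = grid$stop)
  write_target_bedgraph(tt, file.path(out_dir, "gamma.bedgraph"))

  ## stage 3: features (standardized over all bins), windows, split
  fm_all <- {
    vals <- do.call(rbind, lapply(chrom_data, function(cd) cd$features$values))
    feature_matrix(vals, chrom_data[[1]]$features$mark_names, bins)
  }
  if (!is.null(cfg$feature_set))
    fm_all <- feature_matrix(
      fm_all$values[, cfg$feature_set, drop = FALSE], cfg$feature_set, bins)
  fm_std <- standardize_features(fm_all)
  ds <- make_windows(fm_std, tt, cfg$window_size)
  sp <- split_spec(cfg$split$train, cfg$split$test, cfg$split$val,
                   seed = stage_seed(seed, 7L), mode = cfg$split$mode)
  splits <- split_windows(ds, sp)
  alpha <- compute_alpha(tt$values)$alpha

  ## stage 4: train + evaluate every configured model
  metrics <- list()
  for (mi in seq_along(cfg$models)) {
    m <- cfg$models[[mi]]
    spec <- do.call(model_spec, m)
    train_in <- splits$train; val_in <- splits$val; test_in <- splits$test
    if (spec$family %in% c("constant", "linear", "gboost") &&
        cfg$window_size != 1L) {
      ds1 <- make_windows(fm_std, tt, 1L)
      sp1 <- split_windows(ds1, sp)
      train_in <- sp1$train; val_in <- sp1$val; test_in <- sp1$test
    }
    model <- fit_spec(spec, train_in, val_in, seed = stage_seed(seed, 200L + mi))
    sp_list <- list(train = train_in, val = val_in, test = test_in)
    for (s in names(sp_list)) {
      e <- evaluate_predictions(sp_list[[s]]$targets,
                                predict(model, sp_list[[s]]), alpha)
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = spec$family, model_id = mi, split = s,
        n = e$n, mse = e$mse, mae = e$mae, r2 = e$r2, wmse = e$wmse)
    }
  }
  metrics <- do.call(rbind, metrics)
  write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       digits = NA, dataframe = "rows")

  ## manifest: config + seeds + versions; enough to reproduce the run
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed, alpha = alpha,
    n_bins = nrow(bins), n_windows = dim(ds$windows)[1],
    package_version = as.character(utils::packageVersion("hichipml")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- list(target = tt, metrics = metrics, alpha = alpha, manifest = manifest)
  out <- out_dir
  attr(out, "results") <- res
  invisible(out)
}
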