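#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Any
#' unknown field is rejected by name. Seeds for the individual stages are
#' derived deterministically from the master seed, so a config reproduces
#' its outputs exactly.
#'
#' @param seed Master seed.
#' @param n_envs Number of synthetic base lighting environments.
#' @param env_height Environment-map height in pixels.
#' @param n_shapes Shapes for the factorial gloss set.
#' @param n_observers Simulated observers.
#' @param sessions Sessions per observer.
#' @param resolution Render resolution.
#' @param n_chips Chips for the reflectance basis.
#' @param grid_hues,grid_lightnesses,grid_chromas Color-grid axes.
#' @param k Highlight threshold percent used for the metric table.
#' @param band Contrast sub-band used for the metric table.
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_envs = 12, env_height = 64,
                       n_shapes = 18, n_observers = 10, sessions = 1,
                       resolution = 128, n_chips = 1269,
                       grid_hues = seq(0, 356, by = 4),
                       grid_lightnesses = seq(28, 74, by = 2),
                       grid_chromas = seq(8, 26, by = 2),
                       k = 5, band = 4,
                       out_dir = tempfile("glosscon_run_")) {
  cfg <- list(seed = seed, n_envs = n_envs, env_height = env_height,
              n_shapes = n_shapes, n_observers = n_observers,
              sessions = sessions, resolution = resolution,
              n_chips = n_chips, grid_hues = grid_hues,
              grid_lightnesses = grid_lightnesses,
              grid_chromas = grid_chromas, k = k, band = band,
              out_dir = out_dir)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- c("seed", "n_envs", "env_height", "n_shapes", "n_observers",
             "sessions", "resolution", "n_chips", "grid_hues",
             "grid_lightnesses", "grid_chromas", "k", "band", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(known, names(cfg))
  if (length(missing)) {
    stop("missing config field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(cfg$n_envs >= 1, cfg$env_height >= 16, cfg$resolution >= 16,
            cfg$n_observers >= 1, cfg$sessions >= 1)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("grid_hues", "grid_lightnesses", "grid_chromas")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.numeric(cfg[[f]])
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable small-integer stage seed derived from the master seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 10007L + h) %% .Machine$integer.max
}

write_stage_csv <- function(df, path, config_hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", config_hash), con)
  write.csv(as.data.frame(df), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full synthesis-and-analysis pipeline
#'
#' Executes all stages in order — reflectance basis and color grid,
#' lighting-environment set (natural + gamut-rotated + phase-scrambled),
#' single-object stimuli, factorial gloss stimuli, image metrics,
#' simulated observers, and the constancy analyses — writing stage outputs
#' (CSV with a config-hash comment line, JSON for analysis summaries) and
#' a manifest with a content hash per artifact under `config$out_dir`.
#' Stages whose outputs already exist in the manifest are skipped on
#' rerun, so a partial run resumes where it stopped.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages.
#' @return The run directory, invisibly; stage results are also returned
#'   in the `"results"` attribute.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  say <- function(...) if (!quiet) message("[glosscon] ", ...)
  manifest_path <- file.path(config$out_dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  } else data.frame(file = character(), md5 = character())
  done <- function(f) {
    f %in% manifest$file && file.exists(file.path(config$out_dir, f))
  }
  record <- function(f) {
    md5 <- unname(tools::md5sum(file.path(config$out_dir, f)))
    manifest <<- rbind(manifest[manifest$file != f, ],
                       data.frame(file = f, md5 = md5))
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
  }
  results <- list()

  # stage 1: basis + color grid
  say("stage grid: reflectance basis and color grid")
  chips <- synth_munsell_chips(config$n_chips, seed = stage_seed(config$seed, "chips"))
  basis <- fit_basis(chips, 6, seed = stage_seed(config$seed, "basis"))
  grid <- generate_color_grid(basis, config$grid_hues,
                              config$grid_lightnesses, config$grid_chromas)
  if (!done("grid.csv")) {
    write_color_grid(grid, file.path(config$out_dir, "grid.csv"))
    record("grid.csv")
  }
  results$basis <- basis
  results$grid <- grid

  # stage 2: lighting environments
  say("stage environments: ", config$n_envs, " base maps x 3 conditions")
  envs <- lapply(seq_len(config$n_envs), function(i) {
    synth_envmap(config$env_height,
                 seed = stage_seed(config$seed, paste0("env", i)),
                 cap_azimuth = (i * 97) %% 360,
                 cap_strength = 5 + 4 * (i %% 4),
                 log_sd = 0.6 + 0.1 * (i %% 3),
                 chroma_sd = c(3 + (i %% 3), 9 + 2 * (i %% 4)))
  })
  env_set <- build_env_set(envs, seed = stage_seed(config$seed, "scramble"))
  stats_tbl <- dplyr::bind_cols(
    env_set[, c("env_id", "condition")],
    dplyr::bind_rows(lapply(env_set$env, env_stats)))
  if (!done("env_stats.csv")) {
    write_stage_csv(stats_tbl, file.path(config$out_dir, "env_stats.csv"),
                    config_hash)
    record("env_stats.csv")
  }
  results$env_set <- env_set
  results$env_stats <- stats_tbl

  # stage 3: stimuli
  say("stage scenes: single-object set over ", nrow(env_set), " environments")
  scenes1 <- make_stimuli(env_set, seed = stage_seed(config$seed, "scenes1"),
                          resolution = config$resolution)
  say("stage scenes: factorial set ", config$n_envs, " x ", config$n_shapes)
  nat <- env_set[env_set$condition == "natural", ]
  scenes2 <- make_factorial_stimuli(nat, n_shapes = config$n_shapes,
                                    seed = stage_seed(config$seed, "scenes2"),
                                    resolution = config$resolution)
  for (nm in c("scenes_single.csv", "scenes_factorial.csv")) {
    sc <- if (nm == "scenes_single.csv") scenes1 else scenes2
    if (!done(nm)) {
      write_stage_csv(scene_truth(sc), file.path(config$out_dir, nm), config_hash)
      record(nm)
    }
  }
  results$scenes_single <- scenes1
  results$scenes_factorial <- scenes2

  # stage 4: metrics
  say("stage metrics")
  met1 <- scene_metric_table(scenes1, k = config$k, band = config$band)
  met2 <- scene_metric_table(scenes2, k = config$k, band = config$band)
  for (nm in c("metrics_single.csv", "metrics_factorial.csv")) {
    m <- if (nm == "metrics_single.csv") met1 else met2
    if (!done(nm)) {
      write_stage_csv(m, file.path(config$out_dir, nm), config_hash)
      record(nm)
    }
  }
  results$metrics_single <- met1
  results$metrics_factorial <- met2

  # stage 5: simulated observers
  say("stage simulate: ", config$n_observers, " observers")
  model <- observer_model(n_observers = config$n_observers,
                          seed = stage_seed(config$seed, "observers"))
  main1 <- scenes1[!scenes1$is_control, ]
  set1 <- simulate_observers(scene_truth(main1), met1, model,
                             sessions = config$sessions)
  model2 <- observer_model(
    n_observers = config$n_observers,
    bias = list(pellacini_c = c(truth = 0.45, contrast_aggregate = 0.55)),
    noise_sd = c(pellacini_c = 0.015),
    clamp = list(pellacini_c = c(0, pellacini_c(0.0999, 33.9))),
    seed = stage_seed(config$seed, "observers2"))
  set2 <- simulate_observers(scene_truth(scenes2), met2, model2,
                             sessions = config$sessions)
  for (nm in c("settings_single.csv", "settings_factorial.csv")) {
    s <- if (nm == "settings_single.csv") set1 else set2
    if (!done(nm)) {
      write_stage_csv(s, file.path(config$out_dir, nm), config_hash)
      record(nm)
    }
  }
  results$settings_single <- set1
  results$settings_factorial <- set2

  # stage 6: analysis
  say("stage analyze")
  reports <- lapply(c("hue", "lightness", "chroma", "pellacini_c"),
                    function(p) glance(observer_truth_corr(set1, p)))
  corr_tbl <- dplyr::bind_rows(reports)
  ceilings <- noise_ceiling(set2, "pellacini_c")
  env_slopes <- per_env_slope(
    dplyr::filter(set2, .data$parameter == "pellacini_c"),
    env_of = scene_truth(scenes2)[, c("image_id", "environment")])
  predictors <- met2[, c("image_id", "coverage", "sharpness", "contrast_band",
                         grep("^lum_", names(met2), value = TRUE))]
  reg <- loo_regression(predictors,
                        dplyr::filter(set2, .data$parameter == "pellacini_c"))
  analysis <- list(
    correlation_with_truth = corr_tbl,
    noise_ceiling = ceilings,
    per_environment_slopes = env_slopes,
    loo_regression = list(coefficients = tidy(reg), glance = glance(reg)))
  if (!done("analysis.json")) {
    jsonlite::write_json(analysis, file.path(config$out_dir, "analysis.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    record("analysis.json")
  }
  if (!done("correlations.csv")) {
    write_stage_csv(corr_tbl, file.path(config$out_dir, "correlations.csv"),
                    config_hash)
    record("correlations.csv")
  }
  results$analysis <- analysis

  say("done: ", config$out_dir)
  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}
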