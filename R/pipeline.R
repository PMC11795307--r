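#' @name cli_pipeline
#' @title End-to-end pipeline runs
#'
#' @description
#' `run_pipeline()` orchestrates preprocess -> detect -> filter -> metrics ->
#' network on one movie and writes its outputs (CSV tables, a JSON manifest
#' recording the config and seed, and a log) to a run directory, so that a
#' whole experiment is reproducible from `(inputs, config, seed)`.
#' `aggregate_runs()` collects per-run summaries into one table with a row
#' per experiment, ready for external group-level statistics.
NULL

#' Default pipeline configuration
#'
#' @param ... named overrides of the defaults.
#' @return a named list validated by [validate_config()].
#' @export
default_config <- function(...) {
  cfg <- list(
    window_s = 30,
    detection_method = "gaussian3sd",
    s_low_um = 30,
    s_high_um = 195,
    downsample_factor = 1L,
    ring_mm = c(1.8, 2.2),
    n_events_use = 100L,
    n_surrogates = 100L,
    n_subsets = 10L,
    subset_size = 100L,
    seed_stride = 1L,
    register = FALSE,
    rng_seed = 1L,
    age_group = NA_character_,
    area = NA_character_
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks every numeric field against the range its analysis stage requires,
#' before any computation starts.
#'
#' @param cfg named list as produced by [default_config()] or
#'   [read_config()].
#' @return the config, invisibly normalised.
#' @export
validate_config <- function(cfg) {
  if (cfg$window_s < 10 || cfg$window_s > 64)
    stop_invalid("config: window_s must lie in [10, 64] seconds")
  if (!cfg$detection_method %in% c("gaussian3sd", "percentile80"))
    stop_invalid("config: unknown detection method '", cfg$detection_method, "'")
  if (cfg$s_low_um >= cfg$s_high_um)
    stop_invalid("config: s_low_um must be < s_high_um")
  if (length(cfg$ring_mm) != 2 || cfg$ring_mm[1] >= cfg$ring_mm[2])
    stop_invalid("config: ring_mm must be c(lo, hi) with lo < hi")
  for (f in c("n_events_use", "n_surrogates", "n_subsets", "subset_size",
              "downsample_factor", "seed_stride"))
    if (cfg[[f]] < 1) stop_invalid("config: ", f, " must be >= 1")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg
}

#' Read a YAML pipeline configuration
#'
#' @param path path to a YAML file of [default_config()] fields.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  validate_config(base)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  writeLines(msg, con)
}

#' Run the full analysis pipeline on one movie
#'
#' Stages: optional rigid registration, baseline + dF/F (skipped when the
#' movie is already dF/F), event detection, band-pass filtering, per-event
#' metrics, modularity significance, long-range correlation strength and
#' cross-validated dimensionality. Any stage error aborts with the stage
#' name. Re-running with an identical config and inputs reproduces identical
#' outputs.
#'
#' @param mv a [movie()] (raw or dff).
#' @param roi a [roi_mask()].
#' @param config a validated config list (see [default_config()]).
#' @param outdir run directory to create and write into.
#' @return (invisibly) a list with the run directory and all stage results.
#' @export
run_pipeline <- function(mv, roi, config = default_config(), outdir) {
  config <- validate_config(config)
  check_same_grid(mv, roi)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logf))

  stage <- function(name, expr) {
    log_line(logf, "stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (mv$kind == "raw") {
    if (isTRUE(config$register))
      mv <- stage("register", register_rigid(mv)$movie)
    f0 <- stage("baseline", compute_baseline(mv, config$window_s))
    dff <- stage("dff", compute_dff(mv, f0, roi))
  } else {
    dff <- mv
  }

  catalog <- stage("detect",
    detect_events(dff, roi, method = config$detection_method))
  if (nrow(catalog$events) < 2)
    stop("pipeline stage 'detect' failed: fewer than 2 events detected",
         call. = FALSE)

  metrics <- stage("metrics",
    event_metrics(catalog, roi, config$s_low_um, config$s_high_um,
                  factor = config$downsample_factor))

  modsig <- stage("modularity_significance",
    modularity_significance(metrics$modularity[metrics$valid], dff, catalog,
                            roi, derive_seed(config$rng_seed, "modsig"),
                            s_low_um = config$s_low_um,
                            s_high_um = config$s_high_um,
                            factor = config$downsample_factor))

  pset <- stage("patterns",
    build_pattern_set(catalog$frames_raw, roi, config$s_low_um,
                      config$s_high_um, factor = config$downsample_factor))

  strength <- stage("correlation_strength", suppressWarnings(
    corrected_long_range_strength(pset, n_use = config$n_events_use,
                                  n_surrogates = config$n_surrogates,
                                  ring_mm = config$ring_mm,
                                  rng_seed = derive_seed(config$rng_seed, "ring"),
                                  seed_stride = config$seed_stride)))

  med_wl <- median(metrics$wavelength_mm[metrics$valid])
  dim_res <- stage("dimensionality", suppressWarnings(
    cross_validated_dimensionality(pset, med_wl,
                                   n_subsets = config$n_subsets,
                                   subset_size = config$subset_size,
                                   rng_seed = derive_seed(config$rng_seed, "dim"))))

  network <- tibble::tibble(
    variance_real = strength$variance_real,
    variance_surrogate = strength$variance_surrogate,
    variance_corrected = strength$variance_real - strength$variance_surrogate,
    p_corr = strength$p_value,
    significant_corr = strength$significant,
    d_eff = dim_res$d_eff,
    n_events = nrow(catalog$events),
    n_events_used = strength$n_events_used,
    events_resampled = strength$resampled,
    median_wavelength_mm = med_wl,
    modularity_p = modsig$p_value)

  write.csv(catalog$events, file.path(outdir, "events.csv"),
            row.names = FALSE)
  write.csv(metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
  write.csv(network, file.path(outdir, "network.csv"), row.names = FALSE)

  manifest <- list(
    package = "modmap",
    version = as.character(utils::packageVersion("modmap")),
    config = config,
    rng_seed = config$rng_seed,
    n_frames = dim(mv$data)[1],
    n_events = nrow(catalog$events),
    area = config$area,
    age_group = config$age_group)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(logf, "done: ", nrow(catalog$events), " events")

  invisible(list(outdir = outdir, dff = dff, catalog = catalog,
                 metrics = metrics, modsig = modsig, pset = pset,
                 strength = strength, dimensionality = dim_res,
                 network = network))
}

#' Aggregate several pipeline runs into one table
#'
#' @param run_dirs character vector of run directories written by
#'   [run_pipeline()].
#' @return tibble with one row per run: labels, event counts, median
#'   wavelength/modularity, mean module amplitude, correlation strength,
#'   dimensionality and significance flags.
#' @export
aggregate_runs <- function(run_dirs) {
  if (!length(run_dirs)) stop_invalid("no run directories given")
  rows <- list()
  for (rd in run_dirs) {
    mf <- file.path(rd, "manifest.json")
    if (!file.exists(mf)) {
      warning("skipping ", rd, ": no manifest.json")
      next
    }
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    met <- read.csv(file.path(rd, "metrics.csv"))
    net <- read.csv(file.path(rd, "network.csv"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      run = basename(rd),
      area = man$area %||% NA_character_,
      age_group = man$age_group %||% NA_character_,
      n_events = man$n_events,
      median_wavelength_mm = median(met$wavelength_mm[met$valid], na.rm = TRUE),
      median_modularity = median(met$modularity[met$valid], na.rm = TRUE),
      mean_module_amplitude = mean(met$module_amplitude, na.rm = TRUE),
      modularity_p = net$modularity_p,
      modularity_significant = net$modularity_p < 0.05,
      variance_real = net$variance_real,
      variance_surrogate = net$variance_surrogate,
      variance_corrected = net$variance_corrected,
      corr_significant = net$significant_corr,
      d_eff = net$d_eff,
      rng_seed = man$rng_seed)
  }
  if (!length(rows)) stop_invalid("no readable run directories")
  do.call(rbind, rows)
}
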