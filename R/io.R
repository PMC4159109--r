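#' Write / read a synthetic trial to a directory
#'
#' A trial is stored as a per-trial directory: `records.parquet` (an Arrow
#' array container with one row per sample, columns `cycle_index`,
#' `sample`, losslessly round-tripping the doubles), `flow.csv`
#' (`time_s,current_ma`), and `metadata.json` (seed, configuration, true
#' rupture instant, per-cycle intensities). `read_trial()` validates the
#' container: a missing sampling rate or a non-monotone flow time axis is
#' a format error.
#'
#' @param trial A `pcd_trial` from [generate_trial()] (records must have
#'   been kept).
#' @param path Directory to create/fill.
#' @return `write_trial()` returns `path` invisibly; `read_trial()`
#'   returns a `pcd_trial`.
#' @export
write_trial <- function(trial, path) {
  rlang::check_installed("arrow", reason = "to store PCD records")
  if (is.null(trial$cycles$record)) {
    abort("trial was generated without keep_records = TRUE",
          class = "pcd_input_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  recs <- trial$cycles$record
  nper <- lengths(lapply(recs, `[[`, "samples"))
  tab <- tibble(
    cycle_index = rep(trial$cycles$cycle_index, nper),
    sample = unlist(lapply(recs, `[[`, "samples"))
  )
  arrow::write_parquet(tab, file.path(path, "records.parquet"))
  noise <- tibble(cycle_index = -1L,
                  sample = trial$noise_reference$samples)
  arrow::write_parquet(noise, file.path(path, "noise_reference.parquet"))
  utils::write.csv(trial$flow_trace, file.path(path, "flow.csv"),
                   row.names = FALSE)
  meta <- list(
    trial_id = trial$trial_id,
    seed = trial$seed,
    sampling_rate = trial$config$sampling_rate,
    true_rupture_instant = trial$true_rupture_instant,
    exposure_schedule = trial$exposure_schedule,
    config = unclass(trial$config)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  rlang::check_installed("arrow", reason = "to read PCD records")
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) {
    abort("not a trial directory: metadata.json missing",
          class = "pcd_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    abort("metadata is missing the sampling_rate attribute",
          class = "pcd_format_error")
  }
  cfg_fields <- meta$config
  cfg_fields$band_base_amplitudes <- unlist(cfg_fields$band_base_amplitudes)
  cfg_fields$growth_rates <- unlist(cfg_fields$growth_rates)
  cfg_fields$burst_weights <- unlist(cfg_fields$burst_weights)
  cfg_fields$amplitude_jitter <- unlist(cfg_fields$amplitude_jitter)
  config <- do.call(synth_config, cfg_fields)
  flow <- as_tibble(utils::read.csv(file.path(path, "flow.csv")))
  if (any(diff(flow$time_s) <= 0)) {
    abort("flow trace time axis is not strictly increasing",
          class = "pcd_format_error")
  }
  attr(flow, "sonication_start") <- 0
  class(flow) <- c("pcd_flow_trace", class(flow))
  tab <- arrow::read_parquet(file.path(path, "records.parquet"))
  noise_tab <- arrow::read_parquet(file.path(path, "noise_reference.parquet"))
  sched <- meta$exposure_schedule
  cycles_idx <- sort(unique(tab$cycle_index))
  records <- lapply(cycles_idx, function(ci) {
    structure(
      list(samples = tab$sample[tab$cycle_index == ci],
           sampling_rate = meta$sampling_rate,
           cycle_index = ci,
           trial_id = meta$trial_id,
           intensity = sched[ci + 1L],
           amplitudes = NULL),
      class = "pcd_record")
  })
  noise_ref <- structure(
    list(samples = noise_tab$sample, sampling_rate = meta$sampling_rate,
         cycle_index = -1L, trial_id = meta$trial_id, intensity = 0,
         amplitudes = NULL),
    class = "pcd_record")
  cycles <- tibble(
    cycle_index = cycles_idx,
    time_s = cycles_idx * config$pulse_period,
    intensity = sched[cycles_idx + 1L],
    record = records
  )
  structure(
    list(cycles = cycles, noise_reference = noise_ref, flow_trace = flow,
         true_rupture_instant = meta$true_rupture_instant %||% NA_real_,
         exposure_schedule = sched, handler_results = NULL,
         config = config, seed = meta$seed, trial_id = meta$trial_id),
    class = "pcd_trial")
}

#' Save / load a pipeline run configuration
#'
#' Round-trips a named list of stage parameters (synthetic generator,
#' chain, controller, analysis settings, seeds) through a single
#' human-readable YAML file.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @return `save_run_config()` returns `path` invisibly;
#'   `load_run_config()` the list.
#' @export
save_run_config <- function(config, path) {
  rlang::check_installed("yaml", reason = "to write run configurations")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  rlang::check_installed("yaml", reason = "to read run configurations")
  yaml::read_yaml(path)
}
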