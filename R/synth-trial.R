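#' Simulate one complete exposure trial
#'
#' Runs the full generative model for a single vessel: a pre-insonation
#' noise reference record, then one PCD record per on-cycle at the
#' scheduled intensity, a latent cumulative-dose vessel update per cycle,
#' termination at rupture or schedule end, and a flow-meter trace
#' consistent with the rupture instant.
#'
#' All randomness flows from a single seeded generator with a fixed draw
#' order: (1) the rupture threshold, (2) the noise reference record, then
#' per cycle (3) three log-normal amplitude jitters and (4) the record's
#' phase and spectral noise, and finally (5) the flow-trace fluctuations.
#' The same seed reproduces the trial bit for bit within this
#' implementation.
#'
#' @param config A [synth_config()].
#' @param exposure_schedule Per-cycle SPTP intensity, W/cm^2. A single
#'   value is recycled to `max_cycles`. Length must not exceed
#'   `max_cycles`.
#' @param seed Integer seed for the trial.
#' @param keep_records Keep the raw records in the result (set `FALSE`
#'   together with `record_handler` to stream long trials without holding
#'   every trace in memory).
#' @param record_handler Optional `function(record, noise_reference)`
#'   called on each record as it is generated; returned values are
#'   collected in `handler_results`.
#' @param trial_id Identifier attached to records and outputs.
#' @return A `pcd_trial`: list with `cycles` (tibble: `cycle_index`,
#'   `time_s`, `intensity`, list-column `record` when kept),
#'   `noise_reference`, `flow_trace`, `true_rupture_instant` (`NA` if no
#'   rupture), `exposure_schedule`, `handler_results`, `config`, `seed`.
#' @examples
#' cfg <- desk_config(record_duration = 0.005, max_cycles = 30)
#' tr <- generate_trial(cfg, 21980, seed = 7)
#' nrow(tr$cycles)
#' @export
generate_trial <- function(config, exposure_schedule, seed,
                           keep_records = TRUE, record_handler = NULL,
                           trial_id = paste0("trial-", seed)) {
  validate_synth_config(config)
  if (length(exposure_schedule) == 1) {
    exposure_schedule <- rep(exposure_schedule, config$max_cycles)
  }
  if (length(exposure_schedule) > config$max_cycles) {
    abort("exposure schedule longer than max_cycles",
          class = "pcd_input_error")
  }
  withr::with_seed(seed, {
    vessel <- vessel_init(config)
    noise_ref <- noise_reference_record(config, trial_id)
    n_sched <- length(exposure_schedule)
    records <- if (keep_records) vector("list", n_sched) else NULL
    handler_results <- if (!is.null(record_handler)) {
      vector("list", n_sched)
    }
    amps_used <- vector("list", n_sched)
    n_run <- 0L
    for (ci in seq_len(n_sched)) {
      t0 <- (ci - 1L) * config$pulse_period
      jit <- rlnorm(3, 0, config$amplitude_jitter)
      amps <- emission_amplitudes(config, t0, exposure_schedule[ci], jit)
      rec <- generate_pcd_record(config, ci - 1L, exposure_schedule[ci],
                                 amplitudes = amps, trial_id = trial_id)
      if (!is.null(record_handler)) {
        handler_results[[ci]] <- record_handler(rec, noise_ref)
      }
      if (keep_records) {
        attr(rec, "spectrum") <- NULL   # keep stored trials light
        records[[ci]] <- rec
      }
      amps_used[[ci]] <- amps
      n_run <- ci
      vessel <- update_vessel(vessel, amps, config, dt = config$pulse_period)
      if (vessel$ruptured) break
    }
    flow <- generate_flow_trace(vessel$rupture_instant, config,
                                duration = n_run + config$rupture_detection_lag + 2)
    cycles <- tibble(
      cycle_index = 0:(n_run - 1L),
      time_s = (0:(n_run - 1L)) * config$pulse_period,
      intensity = exposure_schedule[seq_len(n_run)]
    )
    if (keep_records) cycles$record <- records[seq_len(n_run)]
    cycles$amplitudes <- amps_used[seq_len(n_run)]
    structure(
      list(cycles = cycles,
           noise_reference = noise_ref,
           flow_trace = flow,
           true_rupture_instant = vessel$rupture_instant,
           exposure_schedule = exposure_schedule,
           handler_results = if (!is.null(record_handler)) {
             handler_results[seq_len(n_run)]
           },
           config = config,
           seed = seed,
           trial_id = trial_id),
      class = "pcd_trial")
  })
}

#' @export
print.pcd_trial <- function(x, ...) {
  cat(sprintf("<pcd_trial> %s: %d cycles, %s\n", x$trial_id, nrow(x$cycles),
              if (is.na(x$true_rupture_instant)) "no rupture" else
                sprintf("rupture at %g s", x$true_rupture_instant)))
  invisible(x)
}

#' Simulate a trial directly to band-SNR time series
#'
#' Streams a trial through the spectral stage as it is generated: each
#' record is reduced to its per-band SNR against the trial's noise
#' reference and then discarded, so long trials never hold raw traces in
#' memory. Equivalent to `generate_trial()` followed by
#' [emission_time_series()].
#'
#' @inheritParams generate_trial
#' @param segment_length DFT segment length in samples (see
#'   [averaged_power_spectrum()]).
#' @param bands Band definition tibble, by default [emission_bands()].
#' @return A list: `levels` (a `band_levels` tibble: `trial_id`, `time_s`,
#'   `band`, `snr_db`), `flow_trace`, `true_rupture_instant`, `seed`.
#' @examples
#' cfg <- desk_config(record_duration = 0.005, max_cycles = 20)
#' sim <- simulate_band_levels(cfg, 21980, seed = 3)
#' head(sim$levels)
#' @export
simulate_band_levels <- function(config, exposure_schedule, seed,
                                 segment_length = 5000,
                                 bands = emission_bands(),
                                 trial_id = paste0("trial-", seed)) {
  noise_energy <- NULL
  handler <- function(rec, noise_ref) {
    if (is.null(noise_energy)) {
      nspec <- averaged_power_spectrum(noise_ref, segment_length)
      noise_energy <<- vapply(seq_len(nrow(bands)), function(i) {
        band_energy(nspec, bands[i, ])
      }, numeric(1))
    }
    spec <- averaged_power_spectrum(rec, segment_length)
    sig <- vapply(seq_len(nrow(bands)), function(i) {
      band_energy(spec, bands[i, ])
    }, numeric(1))
    10 * log10(sig / noise_energy)
  }
  trial <- generate_trial(config, exposure_schedule, seed,
                          keep_records = FALSE, record_handler = handler,
                          trial_id = trial_id)
  snr <- do.call(rbind, trial$handler_results)
  levels <- tibble(
    trial_id = trial_id,
    time_s = rep(trial$cycles$time_s, times = nrow(bands)),
    band = rep(bands$band, each = nrow(snr)),
    snr_db = as.vector(snr)
  ) |> dplyr::arrange(.data$time_s, .data$band)
  class(levels) <- c("band_levels", class(levels))
  list(levels = levels,
       flow_trace = trial$flow_trace,
       true_rupture_instant = trial$true_rupture_instant,
       seed = seed)
}
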