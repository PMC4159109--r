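#' Latent vessel-damage state
#'
#' The vessel is modeled by a cumulative cavitation dose with a per-trial
#' random rupture threshold. The threshold is drawn once, at trial start,
#' from a log-normal distribution (`hazard_scale` = meanlog, `hazard_shape`
#' = sdlog); `vessel_init()` consumes exactly one draw from the session
#' RNG. Setting `hazard_scale = Inf` disables rupture entirely.
#'
#' @param config A [synth_config()].
#' @return A `vessel_state`: list with `cumulative_dose`, `threshold`,
#'   `ruptured`, `rupture_instant` (s, `NA` until rupture), `elapsed` (s).
#' @examples
#' withr::with_seed(1, vessel_init(desk_config()))$threshold
#' @export
vessel_init <- function(config) {
  threshold <- if (is.infinite(config$hazard_scale)) Inf else
    rlnorm(1, config$hazard_scale, config$hazard_shape)
  structure(
    list(cumulative_dose = 0, threshold = threshold, ruptured = FALSE,
         rupture_instant = NA_real_, elapsed = 0),
    class = "vessel_state")
}

#' Advance the vessel-damage process by one exposure interval
#'
#' Adds `((A_subharmonic + w * A_broadband) / dose_ref_amplitude)^dose_exponent
#' * dt` to the cumulative dose, with `w = dose_broadband_weight`. The
#' superlinear exponent encodes that sustained high-amplitude cavitation is
#' disproportionately damaging; it is what lets the feedback controller,
#' which caps emission amplitude, nearly stall damage accumulation. The
#' subharmonic (stable cavitation) amplitude carries full weight and the
#' broadband (inertial cavitation) amplitude a reduced one. The vessel ruptures the first time the
#' dose reaches the trial's threshold; the rupture instant is recorded at
#' the end of the interval (1-s resolution under the default protocol).
#'
#' @param state A `vessel_state` from [vessel_init()].
#' @param band_amplitudes Named class-amplitude vector (V) for the interval
#'   (typically the jittered amplitudes of the cycle's record).
#' @param config A [synth_config()].
#' @param dt Interval length, s (> 0).
#' @return The updated `vessel_state`.
#' @examples
#' cfg <- desk_config()
#' st <- withr::with_seed(1, vessel_init(cfg))
#' st <- update_vessel(st, emission_amplitudes(cfg, 0, 21980), cfg)
#' st$cumulative_dose
#' @export
update_vessel <- function(state, band_amplitudes, config, dt = 1) {
  stopifnot(dt > 0)
  rate <- ((band_amplitudes[["subharmonic"]] +
              config$dose_broadband_weight * band_amplitudes[["broadband"]]) /
             config$dose_ref_amplitude)^config$dose_exponent
  state$cumulative_dose <- state$cumulative_dose + rate * dt
  state$elapsed <- state$elapsed + dt
  if (!state$ruptured && state$cumulative_dose >= state$threshold) {
    state$ruptured <- TRUE
    state$rupture_instant <- state$elapsed
  }
  state
}
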