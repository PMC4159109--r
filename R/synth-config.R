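#' Configuration of the synthetic cavitation-emission generator
#'
#' Builds the parameter set that drives every synthetic object in the
#' package: passive cavitation detector (PCD) voltage records, the latent
#' vessel-damage ("dose") process that decides when a vessel ruptures, and
#' the 1-Hz flow-meter trace used to detect rupture.
#'
#' The generator emulates a pulsed exposure protocol: 0.5-s insonation
#' cycles alternating with 0.5-s pauses (1 Hz pulse repetition, 50% duty
#' cycle) for up to `max_cycles` cycles or until rupture. Each on-cycle
#' yields one PCD record containing an electronic noise floor, band-limited
#' low-frequency (10--30 kHz) and broadband (0.3--1.1 MHz) Gaussian noise
#' components, and a subharmonic tone at 1.65 MHz (half the 3.3-MHz drive
#' frequency). Class amplitudes grow linearly with elapsed exposure time,
#' scale with focal intensity through a power law, carry multiplicative
#' log-normal cycle-to-cycle jitter, and include an initial burst that
#' decays over the first seconds of exposure (residual gas bubbles being
#' eliminated by the first sonications).
#'
#' Vessel rupture is modeled as a cumulative dose process: each 1-s cycle
#' adds `((A_sub + w A_broad) / dose_ref_amplitude)^dose_exponent` (times
#' `dt`, with `w = dose_broadband_weight`) to the dose, and the vessel ruptures when the dose first crosses a
#' per-trial threshold drawn once from a log-normal with meanlog
#' `hazard_scale` and sdlog `hazard_shape`. The superlinear exponent makes
#' sustained high-amplitude cavitation disproportionately damaging, so
#' suppressing emission amplitude (as the feedback controller does) nearly
#' stalls the dose.
#'
#' @param sampling_rate Sampling rate of PCD records, Hz. Must exceed twice
#'   the subharmonic frequency so the 1.65-MHz tone is representable.
#' @param record_duration Duration of each on-cycle record, s. The
#'   experimental protocol records 0.5 s; desk-scale analyses use shorter
#'   records (e.g. 0.05 s) without changing any other dynamics, because the
#'   rupture process advances per cycle, not per sample.
#' @param pulse_period Pulse repetition period, s (1 s: 50% duty cycle with
#'   0.5-s on-time).
#' @param max_cycles Maximum number of on-cycles per trial (300 cycles = 5
#'   min at 1 Hz).
#' @param noise_floor_rms RMS of the electronic noise floor, V.
#' @param band_base_amplitudes Named numeric vector, V: emission amplitude of
#'   each class (`low_frequency`, `broadband`, `subharmonic`) at time zero
#'   and reference intensity. Band amplitudes are RMS for the noise-like
#'   classes and peak amplitude for the subharmonic tone.
#' @param growth_rates Named numeric vector, V/s: linear amplitude growth of
#'   each class with elapsed exposure time.
#' @param intensity_coupling Dimensionless exponent linking spatial-peak
#'   temporal-peak (SPTP) focal intensity to emission amplitude:
#'   amplitudes scale as `(intensity / intensity_ref)^intensity_coupling`.
#' @param intensity_ref Reference SPTP intensity, W/cm^2, at which the base
#'   amplitudes apply.
#' @param initial_burst_amplitude Amplitude of the initial emission burst, V
#'   (set to 0, or `burst_enabled = FALSE`, to disable).
#' @param initial_burst_decay Exponential decay time of the burst, s.
#' @param burst_weights Named numeric vector: per-class multipliers on the
#'   burst amplitude. Defaults reflect bursts being largest at low
#'   frequency and smallest in the broadband band.
#' @param burst_enabled Logical; include the initial burst term.
#' @param amplitude_jitter Standard deviation (log scale) of multiplicative
#'   cycle-to-cycle amplitude jitter, applied independently per class. A
#'   scalar applies to all classes; a named length-3 vector sets each class
#'   separately. The defaults make the sustained subharmonic emission
#'   steadier than the spiky, collapse-driven broadband emission.
#' @param dose_exponent Exponent of the dose-amplitude law (superlinear
#'   damage accumulation).
#' @param dose_broadband_weight Relative weight of the broadband amplitude
#'   in the damage dose (subharmonic weight is 1): stable-cavitation
#'   activity is the dominant driver of wall damage, with inertial
#'   cavitation contributing secondarily.
#' @param dose_ref_amplitude Amplitude scale, V, normalizing the dose rate.
#' @param hazard_scale Meanlog of the log-normal per-trial rupture
#'   threshold (log dose units).
#' @param hazard_shape Sdlog of the per-trial rupture threshold.
#' @param flow_baseline Flow-meter output current baseline, mA.
#' @param flow_fluctuation Fractional peak fluctuation of the flow current
#'   for an intact vessel (about +/-1%); must stay below the 3% detection
#'   drop so fluctuation alone can never trigger detection.
#' @param rupture_detection_lag Delay, s, between the rupture instant and
#'   the first flow sample below the 3% drop (measured as 8 s).
#' @param subharmonic_freq Subharmonic frequency, Hz.
#'
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(record_duration = 0.01)
#' cfg$sampling_rate
#' @seealso [desk_config()] for the reduced desk-scale defaults used
#'   throughout the package's examples and tests.
#' @export
synth_config <- function(sampling_rate = 1e7,
                         record_duration = 0.5,
                         pulse_period = 1,
                         max_cycles = 300,
                         noise_floor_rms = 2e-6,
                         band_base_amplitudes = c(low_frequency = 4e-6,
                                                  broadband = 2e-6,
                                                  subharmonic = 1e-6),
                         growth_rates = c(low_frequency = 5e-8,
                                          broadband = 1.3e-7,
                                          subharmonic = 6e-7),
                         intensity_coupling = 2,
                         intensity_ref = 20570,
                         initial_burst_amplitude = 3e-6,
                         initial_burst_decay = 5,
                         burst_weights = c(low_frequency = 1,
                                           broadband = 0.2,
                                           subharmonic = 0.3),
                         burst_enabled = TRUE,
                         amplitude_jitter = c(low_frequency = 0.25,
                                              broadband = 0.3,
                                              subharmonic = 0.15),
                         dose_exponent = 3,
                         dose_broadband_weight = 0.3,
                         dose_ref_amplitude = 1e-6,
                         hazard_scale = 13.19,
                         hazard_shape = 1.1,
                         flow_baseline = 10,
                         flow_fluctuation = 0.01,
                         rupture_detection_lag = 8,
                         subharmonic_freq = 1.65e6) {
  # unnamed length-3 vectors are taken in canonical band order
  canon <- function(v) {
    if (is.null(names(v))) names(v) <- band_names()
    v[band_names()]
  }
  band_base_amplitudes <- canon(band_base_amplitudes)
  growth_rates <- canon(growth_rates)
  burst_weights <- canon(burst_weights)
  if (length(amplitude_jitter) == 1) {
    amplitude_jitter <- rep(amplitude_jitter, 3)
  }
  amplitude_jitter <- canon(amplitude_jitter)
  cfg <- list(
    sampling_rate = sampling_rate,
    record_duration = record_duration,
    pulse_period = pulse_period,
    max_cycles = max_cycles,
    noise_floor_rms = noise_floor_rms,
    band_base_amplitudes = band_base_amplitudes,
    growth_rates = growth_rates,
    intensity_coupling = intensity_coupling,
    intensity_ref = intensity_ref,
    initial_burst_amplitude = initial_burst_amplitude,
    initial_burst_decay = initial_burst_decay,
    burst_weights = burst_weights,
    burst_enabled = burst_enabled,
    amplitude_jitter = amplitude_jitter,
    dose_exponent = dose_exponent,
    dose_broadband_weight = dose_broadband_weight,
    dose_ref_amplitude = dose_ref_amplitude,
    hazard_scale = hazard_scale,
    hazard_shape = hazard_shape,
    flow_baseline = flow_baseline,
    flow_fluctuation = flow_fluctuation,
    rupture_detection_lag = rupture_detection_lag,
    subharmonic_freq = subharmonic_freq
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Desk-scale generator configuration
#'
#' The full experimental scale (10-MHz sampling, 0.5-s records, i.e. 5e6
#' samples per cycle) is supported but slow for simulation studies. The
#' desk scale keeps the pulse protocol, the emission model and the rupture
#' process identical, and shortens each record to 0.05 s at 3.75-MHz
#' sampling (187,500 samples; still above the 3.3-MHz Nyquist requirement
#' for the 1.65-MHz subharmonic). At this rate the subharmonic sits exactly
#' on the 750-Hz bin grid of 5,000-sample segments, just as it sits on the
#' 2-kHz grid at the full experimental scale, so the single-bin subharmonic
#' measurement suffers no scalloping loss.
#'
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @examples
#' desk_config()$record_duration
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 3.75e6, record_duration = 0.05)
  do.call(synth_config, utils::modifyList(defaults, args))
}

validate_synth_config <- function(cfg) {
  if (cfg$sampling_rate <= 0 || cfg$record_duration <= 0) {
    abort("sampling_rate and record_duration must be positive",
          class = "pcd_config_error")
  }
  if (cfg$sampling_rate <= 2 * cfg$subharmonic_freq) {
    abort(sprintf(
      "sampling_rate (%g Hz) must exceed twice the subharmonic frequency (%g Hz)",
      cfg$sampling_rate, cfg$subharmonic_freq), class = "pcd_config_error")
  }
  n <- cfg$sampling_rate * cfg$record_duration
  if (abs(n - round(n)) > 1e-8 || n < 1) {
    abort("record_duration x sampling_rate must be a positive integer",
          class = "pcd_config_error")
  }
  if (cfg$flow_fluctuation >= 0.03) {
    abort("flow_fluctuation must stay below the 3% detection drop",
          class = "pcd_config_error")
  }
  amps <- c(cfg$noise_floor_rms, cfg$band_base_amplitudes,
            cfg$initial_burst_amplitude)
  if (anyNA(amps) || any(amps < 0)) {
    abort("all amplitudes must be non-negative", class = "pcd_config_error")
  }
  invisible(cfg)
}

band_names <- function() c("low_frequency", "broadband", "subharmonic")

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  sampling: %g Hz, records %g s (%g samples), up to %d cycles\n",
              x$sampling_rate, x$record_duration,
              x$sampling_rate * x$record_duration, x$max_cycles))
  cat(sprintf("  noise floor %.3g V rms; base amplitudes [%s] V\n",
              x$noise_floor_rms,
              paste(signif(x$band_base_amplitudes, 3), collapse = ", ")))
  cat(sprintf("  hazard: lognormal(meanlog %.3g, sdlog %.3g), dose exponent %g\n",
              x$hazard_scale, x$hazard_shape, x$dose_exponent))
  invisible(x)
}
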