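#' Frequency band definitions shared by the generator and the analysis
#'
#' Three emission classes are quantified: a low-frequency band (10--30 kHz,
#' associated with tissue/fluid vaporization), a broadband band
#' (0.3--1.1 MHz, inertial cavitation), and the subharmonic (a single
#' spectral bin at 1.65 MHz, stable cavitation at half the 3.3-MHz drive
#' frequency). The subharmonic band is encoded with `f_low == f_high`; band
#' integration resolves it to the single bin nearest that frequency.
#'
#' @return A tibble with columns `band`, `f_low`, `f_high` (Hz).
#' @examples
#' emission_bands()
#' @export
emission_bands <- function() {
  tibble(
    band = factor(band_names(), levels = band_names()),
    f_low = c(10e3, 0.3e6, 1.65e6),
    f_high = c(30e3, 1.1e6, 1.65e6)
  )
}

#' Deterministic emission amplitude model
#'
#' Class amplitude at elapsed exposure time `t` and SPTP focal intensity
#' `intensity`:
#' `(base + growth * t) * (intensity / intensity_ref)^intensity_coupling * jitter`
#' plus, when enabled, the class-weighted initial burst
#' `burst_weight * initial_burst_amplitude * exp(-t / initial_burst_decay)`.
#'
#' @param config A [synth_config()].
#' @param t Elapsed exposure time, s (cycle start).
#' @param intensity SPTP focal intensity, W/cm^2.
#' @param jitter Optional multiplicative jitter per class (length 3);
#'   defaults to 1 (no jitter), making the result deterministic.
#' @return Named numeric vector of class amplitudes (V).
#' @examples
#' emission_amplitudes(desk_config(), t = 10, intensity = 21980)
#' @export
emission_amplitudes <- function(config, t, intensity, jitter = c(1, 1, 1)) {
  stopifnot(intensity >= 0, t >= 0)
  fac <- if (intensity == 0) 0 else
    (intensity / config$intensity_ref)^config$intensity_coupling
  amps <- (config$band_base_amplitudes + config$growth_rates * t) * fac * jitter
  if (config$burst_enabled && config$initial_burst_amplitude > 0) {
    amps <- amps + config$burst_weights * config$initial_burst_amplitude *
      exp(-t / config$initial_burst_decay)
  }
  names(amps) <- band_names()
  amps
}

# Half-spectrum synthesis: one complex-normal draw per bin, scaled so the
# white floor has the requested RMS and each band-limited component carries
# its full variance uniformly over its (brick-wall) band. The subharmonic
# tone is placed deterministically on the bin nearest its frequency (bin
# quantization error <= fs/2n). Returns the full hermitian DFT.
synth_grid <- function(n, fs, bands) {
  cache_get(sprintf("grid|%d|%g", n, fs), function() {
    half <- n %/% 2L
    m <- half - 1L
    freq <- (1:m) * fs / n
    sel <- lapply(seq_len(nrow(bands)), function(i) {
      if (bands$f_low[i] == bands$f_high[i]) return(integer(0))
      which(freq >= bands$f_low[i] & freq <= bands$f_high[i])
    })
    list(half = half, m = m, band_sel = sel,
         band_n = vapply(sel, length, integer(1)))
  })
}

synth_spectrum <- function(n, fs, noise_rms, band_amps, tone_amp, tone_freq,
                          phase, bands) {
  g <- synth_grid(n, fs, bands)
  sd2 <- rep(n * noise_rms^2 / 2, g$m)  # white floor variance per Re/Im part
  for (i in seq_len(nrow(bands))) {
    if (band_amps[i] <= 0 || g$band_n[i] == 0) next
    sel <- g$band_sel[[i]]
    sd2[sel] <- sd2[sel] + n^2 * band_amps[i]^2 / (4 * g$band_n[i])
  }
  s <- sqrt(sd2)
  xk <- complex(real = s * rnorm(g$m), imaginary = s * rnorm(g$m))
  if (tone_amp > 0) {
    k0 <- round(tone_freq * n / fs)
    k0 <- max(1L, min(g$m, k0))
    # A*sin(w t + phase) contributes -i * (n A / 2) * exp(i phase) at +k0
    xk[k0] <- xk[k0] + (n * tone_amp / 2) * exp(1i * (phase - pi / 2))
  }
  spec <- complex(length.out = n)
  spec[2:(g$half)] <- xk
  spec[n:(g$half + 2L)] <- Conj(xk)    # hermitian mirror; DC and Nyquist = 0
  spec
}

#' Generate one synthetic PCD record
#'
#' Synthesizes a single on-cycle passive cavitation detector voltage trace:
#' electronic noise floor plus band-limited low-frequency and broadband
#' Gaussian noise plus the 1.65-MHz subharmonic tone, with amplitudes from
#' [emission_amplitudes()] (quasi-static within the 0.5-s record). The
#' record is built in the frequency domain (exact band-limited components)
#' and carries its DFT as an attribute so downstream spectral stages can
#' reuse it.
#'
#' Draw order (from the session RNG): tone phase (1 uniform), then the
#' in-phase and quadrature spectral noise components (2 Gaussian vectors).
#' The same RNG state therefore reproduces the record bit for bit.
#'
#' @param config A [synth_config()].
#' @param cycle_index 0-based cycle number; elapsed time is
#'   `cycle_index * pulse_period`.
#' @param intensity SPTP focal intensity for this cycle, W/cm^2.
#' @param amplitudes Optional named class-amplitude vector overriding the
#'   deterministic model (used by [generate_trial()] to inject jitter).
#' @param trial_id Identifier stored with the record.
#' @param compute_samples Materialize the time-domain samples (default).
#'   Streaming consumers that work entirely on the record's cached
#'   spectrum (such as the closed-loop driver) can skip the inverse
#'   transform.
#' @return A `pcd_record`: list with `samples` (V), `sampling_rate`,
#'   `cycle_index`, `trial_id`, `intensity`, `amplitudes`.
#' @examples
#' cfg <- desk_config(record_duration = 0.005)
#' rec <- withr::with_seed(1, generate_pcd_record(cfg, 0, 21980))
#' sd(rec$samples)
#' @export
generate_pcd_record <- function(config, cycle_index, intensity,
                                amplitudes = NULL, trial_id = NA_character_,
                                compute_samples = TRUE) {
  stopifnot(cycle_index >= 0, intensity >= 0)
  validate_synth_config(config)
  n <- as.integer(round(config$sampling_rate * config$record_duration))
  t0 <- cycle_index * config$pulse_period
  if (is.null(amplitudes)) {
    amplitudes <- emission_amplitudes(config, t0, intensity)
  }
  phase <- runif(1, 0, 2 * pi)
  bands <- emission_bands()
  spec <- synth_spectrum(n, config$sampling_rate, config$noise_floor_rms,
                         amplitudes[band_names()],
                         tone_amp = amplitudes[["subharmonic"]],
                         tone_freq = config$subharmonic_freq,
                         phase = phase, bands = bands)
  samples <- if (compute_samples) Re(fft(spec, inverse = TRUE)) / n
  rec <- structure(
    list(samples = samples,
         sampling_rate = config$sampling_rate,
         cycle_index = cycle_index,
         trial_id = trial_id,
         intensity = intensity,
         amplitudes = amplitudes),
    class = "pcd_record")
  attr(rec, "spectrum") <- spec
  rec
}

#' Pre-insonation noise reference record
#'
#' A record containing only the electronic noise floor (all emission
#' classes at zero amplitude), emulating the reference signal acquired
#' before insonation with the function generator off. Processed identically
#' to signal records, it provides the denominator of every band SNR.
#'
#' @param config A [synth_config()].
#' @param trial_id Identifier stored with the record.
#' @return A `pcd_record`.
#' @export
noise_reference_record <- function(config, trial_id = NA_character_) {
  generate_pcd_record(config, cycle_index = 0, intensity = 0,
                      amplitudes = c(low_frequency = 0, broadband = 0,
                                     subharmonic = 0),
                      trial_id = trial_id)
}

#' @export
print.pcd_record <- function(x, ...) {
  cat(sprintf("<pcd_record> cycle %d, %g samples at %g Hz, intensity %g W/cm^2\n",
              x$cycle_index, length(x$samples), x$sampling_rate, x$intensity))
  invisible(x)
}
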