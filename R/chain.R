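#' Analog monitoring-chain configuration
#'
#' Parameters of the subharmonic monitoring chain used by the feedback
#' controller: a 1.65-MHz bandpass filter, preamplification, half-wave
#' rectification, AM demodulation (envelope detection) with a 1,063-Hz
#' cutoff, and digitization at 68.6 kHz. The rupture-prediction recording
#' chain differs only in gain (100 instead of 20,000) and has no bandpass;
#' both share the preamplifier's 10-kHz high-pass (12 dB/octave).
#'
#' @param bandpass_center Bandpass center frequency, Hz.
#' @param bandpass_fractional_bw Fractional bandwidth of the bandpass
#'   (bandwidth = fraction x center). The hardware value is unpublished;
#'   0.10 is a conventional choice for a tuned stage.
#' @param bandpass_order Butterworth order of the bandpass prototype.
#' @param preamp_gain Amplitude gain (20,000 for the suppression chain).
#' @param highpass_cutoff Preamp high-pass cutoff, Hz (12 dB/octave =
#'   2nd-order Butterworth).
#' @param demod_cutoff AM demodulator (envelope detector) cutoff, Hz.
#' @param adc_rate Digitizer sampling rate, Hz.
#' @return A list of class `chain_config`.
#' @examples
#' chain_config()$preamp_gain
#' @export
chain_config <- function(bandpass_center = 1.65e6,
                         bandpass_fractional_bw = 0.10,
                         bandpass_order = 2,
                         preamp_gain = 20000,
                         highpass_cutoff = 10e3,
                         demod_cutoff = 1063,
                         adc_rate = 68.6e3) {
  stopifnot(preamp_gain > 0, bandpass_center > 0, adc_rate > 0)
  structure(
    list(bandpass_center = bandpass_center,
         bandpass_fractional_bw = bandpass_fractional_bw,
         bandpass_order = bandpass_order,
         preamp_gain = preamp_gain,
         highpass_cutoff = highpass_cutoff,
         demod_cutoff = demod_cutoff,
         adc_rate = adc_rate),
    class = "chain_config")
}

# Analytic Butterworth magnitude responses evaluated on the DFT grid. The
# linear stages are applied zero-phase in the frequency domain (a
# frequency-sampled realization of forward-backward filtering), so only
# their magnitude matters.
butterworth_bandpass_mag2 <- function(f, center, frac_bw, order) {
  bw <- frac_bw * center
  x <- (f^2 - center^2) / pmax(f * bw, .Machine$double.xmin)
  1 / (1 + x^(2 * order))
}

butterworth_highpass_mag2 <- function(f, cutoff, order = 2) {
  r <- (f / cutoff)^(2 * order)
  r / (1 + r)
}

#' Simulate the analog monitoring chain on a PCD record
#'
#' Applies, in order: the preamp high-pass, the 1.65-MHz bandpass
#' (both as zero-phase Butterworth magnitude responses on the record's
#' spectrum), the amplitude gain, half-wave rectification (`max(x, 0)`),
#' a one-pole low-pass AM demodulator at `demod_cutoff`, and resampling to
#' the digitizer rate. For an in-band tone of amplitude `A`, the mean of
#' the demodulated envelope is `A * gain / pi` (the half-wave-rectified
#' sine mean).
#'
#' @param record A `pcd_record` (its cached spectrum is reused when
#'   present).
#' @param chain A [chain_config()].
#' @return Numeric vector of envelope samples at `adc_rate`, with
#'   attribute `sampling_rate`.
#' @examples
#' cfg <- desk_config(record_duration = 0.005)
#' rec <- withr::with_seed(1, generate_pcd_record(cfg, 0, 21980))
#' env <- analog_chain(rec, chain_config())
#' length(env)
#' @export
analog_chain <- function(record, chain) {
  fs <- record$sampling_rate
  if (fs <= 2 * chain$bandpass_center) {
    abort("record sampling rate must exceed twice the bandpass center",
          class = "pcd_config_error")
  }
  spec <- attr(record, "spectrum")
  n <- if (is.null(spec)) length(record$samples) else length(spec)
  if (is.null(spec)) spec <- fft(record$samples)
  h <- cache_get(
    sprintf("chain|%d|%g|%g|%g|%d|%g", n, fs, chain$bandpass_center,
            chain$bandpass_fractional_bw, chain$bandpass_order,
            chain$highpass_cutoff),
    function() {
      k <- 0:(n - 1)
      f <- pmin(k, n - k) * fs / n      # two-sided |frequency| grid
      sqrt(butterworth_highpass_mag2(f, chain$highpass_cutoff) *
             butterworth_bandpass_mag2(f, chain$bandpass_center,
                                       chain$bandpass_fractional_bw,
                                       chain$bandpass_order))
    })
  y <- Re(fft(spec * h, inverse = TRUE)) * (chain$preamp_gain / n)
  y[y < 0] <- 0                          # half-wave rectifier
  a <- exp(-2 * pi * chain$demod_cutoff / fs)
  env <- as.numeric(stats::filter((1 - a) * y, a, method = "recursive",
                                  init = mean(y)))
  # resample onto the digitizer grid (linear interpolation on the
  # uniform input grid)
  pos <- seq(0, (n - 1) / fs, by = 1 / chain$adc_rate) * fs
  i0 <- pmin(floor(pos), n - 2)
  frac <- pos - i0
  out <- env[i0 + 1L] * (1 - frac) + env[i0 + 2L] * frac
  attr(out, "sampling_rate") <- chain$adc_rate
  out
}

#' RMS of a demodulated envelope
#'
#' Root-mean-square of the envelope samples over the insonation period:
#' the scalar subharmonic emission value the controller compares to its
#' threshold once per cycle.
#'
#' @param envelope Numeric envelope samples.
#' @return RMS value (V).
#' @examples
#' rms_envelope(c(3, 4))   # sqrt(12.5)
#' @export
rms_envelope <- function(envelope) {
  if (length(envelope) == 0) {
    abort("empty envelope", class = "pcd_input_error")
  }
  sqrt(mean(envelope^2))
}

#' Derive the controller threshold from labeled RMS values
#'
#' Reproduces the threshold-derivation procedure for the feedback
#' controller: find the corner threshold (simultaneously maximizing
#' sensitivity and specificity) of the RMS emission values for
#' pre-rupture versus intact-vessel cycles, then subtract `k` times the
#' measured RMS noise level to obtain a more conservative deployed
#' threshold (floored at zero).
#'
#' @param data Data frame with an RMS score column and a class column.
#' @param rms,truth Tidy-selected columns (defaults `rms_v`, `class`).
#' @param noise_rms Measured RMS noise level of the chain output, V.
#' @param k Number of noise RMS units subtracted (1.5 in the deployed
#'   protocol).
#' @return A one-row tibble: `corner_threshold`, `threshold` (adjusted),
#'   `sensitivity`, `specificity`, `ppv`, `npv` (metrics at the corner).
#' @export
derive_threshold <- function(data, rms = rms_v, truth = class,
                             noise_rms, k = 1.5) {
  roc <- roc_curve(data, score = {{ rms }}, truth = {{ truth }})
  corner <- corner_threshold(roc)
  tibble(
    corner_threshold = corner$threshold,
    threshold = max(0, corner$threshold - k * noise_rms),
    sensitivity = corner$sensitivity,
    specificity = corner$specificity,
    ppv = corner$ppv,
    npv = corner$npv
  )
}
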