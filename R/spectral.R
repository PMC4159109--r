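#' Averaged power spectrum of a PCD record
#'
#' Splits the record into non-overlapping, rectangular-window segments of
#' `segment_length` samples (a trailing partial segment is discarded),
#' takes the DFT of each segment, and averages the squared magnitudes
#' across segments. The experimental protocol uses 5,000-sample segments,
#' giving 1,000 averaged segments per 0.5-s record at 10-MHz sampling.
#'
#' The declared normalization is `P[k] = mean |X[k]|^2 / N` with `N` the
#' segment length: a unit-amplitude sinusoid centered on bin `k0`
#' contributes `N/4` at `k0` in the one-sided spectrum, and the sum of
#' `P[k]` over all (two-sided) bins equals the mean per-segment energy
#' `sum x^2` (Parseval). Only the one-sided half (DC through Nyquist) is
#' returned; [spectrum_total_power()] restores the two-sided total.
#'
#' @param record A `pcd_record`, or a numeric vector (then `sampling_rate`
#'   must be given).
#' @param segment_length Segment length in samples (even, positive).
#' @param sampling_rate Sampling rate, Hz, when `record` is a bare vector.
#' @return A `power_spectrum`: list with `frequency` (Hz, DC..Nyquist),
#'   `power`, `segment_length`, `n_segments`, `sampling_rate`.
#' @examples
#' fs <- 1e6; t <- seq(0, 0.01 - 1 / fs, by = 1 / fs)
#' ps <- averaged_power_spectrum(sin(2 * pi * 1e5 * t), 1000, fs)
#' ps$power[ps$frequency == 1e5]   # N/4 = 250
#' @export
averaged_power_spectrum <- function(record, segment_length = 5000,
                                    sampling_rate = NULL) {
  if (inherits(record, "pcd_record")) {
    x <- record$samples
    sampling_rate <- record$sampling_rate
  } else {
    x <- as.numeric(record)
    if (is.null(sampling_rate)) {
      abort("sampling_rate is required for a bare sample vector",
            class = "pcd_input_error")
    }
  }
  L <- as.integer(segment_length)
  if (L < 2L || L %% 2L != 0L) {
    abort("segment_length must be a positive even integer",
          class = "pcd_input_error")
  }
  sampling_rate <- as.numeric(sampling_rate)
  nseg <- length(x) %/% L
  if (nseg < 1L) {
    abort("record is shorter than one segment", class = "pcd_input_error")
  }
  segs <- x[seq_len(nseg * L)]
  dim(segs) <- c(L, nseg)
  xf <- mvfft(segs)
  p <- rowMeans(Re(xf)^2 + Im(xf)^2) / L
  half <- L %/% 2L
  structure(
    list(frequency = (0:half) * sampling_rate / L,
         power = p[1:(half + 1L)],
         segment_length = L,
         n_segments = nseg,
         sampling_rate = sampling_rate),
    class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %g-Hz resolution, %d segments averaged\n",
              length(x$frequency), x$sampling_rate / x$segment_length,
              x$n_segments))
  invisible(x)
}

#' @describeIn averaged_power_spectrum Tidy a spectrum into a tibble of
#'   `frequency`, `power`.
#' @param x A `power_spectrum`.
#' @param ... Unused.
#' @method tidy power_spectrum
#' @export
tidy.power_spectrum <- function(x, ...) {
  tibble(frequency = x$frequency, power = x$power)
}

#' Total (two-sided) power of an averaged spectrum
#'
#' Restores the two-sided Parseval sum from the one-sided spectrum by
#' doubling all bins except DC and Nyquist; equals the mean per-segment
#' energy `sum x^2` under the declared normalization.
#'
#' @param spectrum A `power_spectrum`.
#' @return Total power (V^2 x samples).
#' @export
spectrum_total_power <- function(spectrum) {
  p <- spectrum$power
  n <- length(p)
  p[1] + p[n] + 2 * sum(p[2:(n - 1)])
}

#' Band-integrated spectral energy
#'
#' Sums one-sided spectral power over the bins whose center frequency lies
#' in the closed interval `[f_low, f_high]`. The DC bin is always excluded
#' (the preamplifier high-passes at 10 kHz). A tonal band specified with
#' `f_low == f_high` (the subharmonic) resolves to the single bin whose
#' center is nearest that frequency, ties going to the lower bin.
#'
#' @param spectrum A `power_spectrum`.
#' @param band One row of a band tibble (see [emission_bands()]), or a
#'   band name from that table.
#' @return Band energy (same units as the spectrum).
#' @examples
#' cfg <- desk_config(record_duration = 0.005)
#' rec <- withr::with_seed(1, noise_reference_record(cfg))
#' band_energy(averaged_power_spectrum(rec), "broadband")
#' @export
band_energy <- function(spectrum, band) {
  if (is.character(band) || is.factor(band)) {
    bands <- emission_bands()
    band <- bands[bands$band == as.character(band), ]
    if (nrow(band) == 0) {
      abort("unknown band name", class = "pcd_input_error")
    }
  }
  f <- spectrum$frequency
  nyq <- spectrum$sampling_rate / 2
  if (band$f_low > nyq) {
    abort("band lies above the Nyquist frequency", class = "pcd_input_error")
  }
  if (band$f_low == band$f_high) {
    k <- which.min(abs(f - band$f_low))  # which.min takes the lower tie
    if (k == 1L) {
      abort("tonal band resolves to the DC bin", class = "pcd_input_error")
    }
    return(spectrum$power[k])
  }
  sel <- f >= band$f_low & f <= band$f_high & f > 0
  if (!any(sel)) {
    abort("no spectral bins fall inside the band", class = "pcd_input_error")
  }
  sum(spectrum$power[sel])
}

#' Band signal-to-noise ratio in decibels
#'
#' `10 log10` of the ratio of band-integrated signal power to
#' band-integrated power of the pre-insonation noise reference, both
#' computed on identical bin grids.
#'
#' @param signal_spectrum,noise_spectrum `power_spectrum` objects on the
#'   same bin grid.
#' @param band Band row or name (see [band_energy()]).
#' @return SNR in dB.
#' @export
band_snr <- function(signal_spectrum, noise_spectrum, band) {
  if (!isTRUE(all.equal(signal_spectrum$frequency,
                        noise_spectrum$frequency))) {
    abort("signal and noise spectra are on different bin grids",
          class = "pcd_input_error")
  }
  e_noise <- band_energy(noise_spectrum, band)
  if (e_noise <= 0) {
    abort("noise reference has zero energy in this band",
          class = "pcd_snr_error")
  }
  10 * log10(band_energy(signal_spectrum, band) / e_noise)
}

#' Per-cycle band SNR time series
#'
#' Reduces a sequence of on-cycle PCD records to the time-dependent
#' low-frequency, broadband and subharmonic SNR levels (1-s temporal
#' resolution under the default protocol), each referenced to the trial's
#' pre-insonation noise record processed in the same manner.
#'
#' @param records List of `pcd_record` objects (or a `pcd_trial`).
#' @param noise_reference The trial's noise `pcd_record` (taken from the
#'   trial when `records` is a `pcd_trial`).
#' @param bands Band tibble, by default [emission_bands()].
#' @param segment_length Segment length passed to
#'   [averaged_power_spectrum()].
#' @return A `band_levels` tibble: `trial_id`, `time_s`, `band`, `snr_db`.
#' @examples
#' cfg <- desk_config(record_duration = 0.005, max_cycles = 10)
#' tr <- generate_trial(cfg, 21980, seed = 2)
#' emission_time_series(tr)
#' @export
emission_time_series <- function(records, noise_reference = NULL,
                                 bands = emission_bands(),
                                 segment_length = 5000) {
  trial_times <- NULL
  if (inherits(records, "pcd_trial")) {
    if (is.null(noise_reference)) noise_reference <- records$noise_reference
    trial_times <- records$cycles$time_s
    records <- records$cycles$record
  }
  if (is.null(noise_reference)) {
    abort("a noise reference record is required", class = "pcd_input_error")
  }
  rates <- vapply(records, function(r) r$sampling_rate, numeric(1))
  if (length(unique(rates)) > 1) {
    abort("records do not share a sampling rate", class = "pcd_input_error")
  }
  nspec <- averaged_power_spectrum(noise_reference, segment_length)
  noise_energy <- vapply(seq_len(nrow(bands)), function(i) {
    band_energy(nspec, bands[i, ])
  }, numeric(1))
  rows <- purrr::map2_dfr(records, seq_along(records), function(rec, i) {
    spec <- averaged_power_spectrum(rec, segment_length)
    sig <- vapply(seq_len(nrow(bands)), function(b) {
      band_energy(spec, bands[b, ])
    }, numeric(1))
    tibble(
      trial_id = rec$trial_id,
      time_s = if (is.null(trial_times)) rec$cycle_index else trial_times[i],
      band = bands$band,
      snr_db = 10 * log10(sig / noise_energy)
    )
  })
  class(rows) <- c("band_levels", class(rows))
  rows
}

#' Plot band SNR time series
#'
#' @param object A `band_levels` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot band_levels
#' @export
autoplot.band_levels <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_s, y = .data$snr_db,
                               colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trial_id) +
    ggplot2::labs(x = "time (s)", y = "band SNR (dB)", colour = "band")
}
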