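test_that("zero input yields a zero spectrum", {
  ps <- averaged_power_spectrum(numeric(10000), 1000, sampling_rate = 1e6)
  expect_true(all(ps$power == 0))
  expect_equal(ps$n_segments, 10)
})

test_that("a bin-centered unit sinusoid peaks at N/4 under the declared normalization", {
  fs <- 1e7
  n <- 5000 * 20
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10e3 * t)          # 10 kHz sits on a 2-kHz bin grid
  ps <- averaged_power_spectrum(x, 5000, fs)
  k <- which(ps$frequency == 10e3)
  expect_equal(ps$power[k], 5000 / 4, tolerance = 1e-10)
  expect_lt(max(ps$power[-k]), 1e-15 * ps$power[k])
})

test_that("Parseval holds exactly on deterministic input and to 2% on white noise", {
  x <- sin(2 * pi * (1:5000) / 50) + 0.3
  ps <- averaged_power_spectrum(x, 5000, 1e7)
  expect_equal(spectrum_total_power(ps), sum(x^2), tolerance = 1e-12)
  y <- withr::with_seed(1, rnorm(5e5, sd = 2))
  psy <- averaged_power_spectrum(y, 5000, 1e7)
  expect_equal(spectrum_total_power(psy), 4 * 5000, tolerance = 0.02)
})

test_that("band integration follows the closed-interval bin-center rule", {
  # hand-built spectrum: 101 bins at 1-kHz spacing
  ps <- structure(
    list(frequency = seq(0, 100e3, by = 1e3), power = rep(0, 101),
         segment_length = 200, n_segments = 1, sampling_rate = 200e3),
    class = "power_spectrum")
  ps$power[31] <- 7                       # 30 kHz, inside [10, 30] kHz
  expect_equal(band_energy(ps, tibble::tibble(f_low = 10e3, f_high = 30e3)),
               7)
  ps$power[] <- 3                         # uniform: u * B bins
  expect_equal(band_energy(ps, tibble::tibble(f_low = 10e3, f_high = 30e3)),
               3 * 21)
  # full-range band equals the one-sided sum without DC
  expect_equal(band_energy(ps, tibble::tibble(f_low = 1, f_high = 100e3)),
               sum(ps$power[-1]))
  # tonal band takes the single nearest bin, ties to the lower bin
  ps$power[] <- 0; ps$power[51] <- 5
  expect_equal(band_energy(ps, tibble::tibble(f_low = 50e3, f_high = 50e3)),
               5)
  expect_equal(band_energy(ps, tibble::tibble(f_low = 50.5e3,
                                              f_high = 50.5e3)), 5)
  expect_error(band_energy(ps, tibble::tibble(f_low = 150e3, f_high = 160e3)),
               class = "pcd_input_error")
})

test_that("band SNR matches its trivial and closed-form values", {
  cfg <- tiny_config()
  nref <- withr::with_seed(2, noise_reference_record(cfg))
  nspec <- averaged_power_spectrum(nref)
  expect_equal(band_snr(nspec, nspec, "broadband"), 0)
  ps10 <- nspec
  ps10$power <- nspec$power * 10
  expect_equal(band_snr(ps10, nspec, "low_frequency"), 10)
  # noise + in-band tone of known power: the measured band SNR matches the
  # closed form 10 log10(1 + P_tone / P_noise_band). The tone sits on the
  # 750-Hz segment bin grid inside the broadband band (many-bin band, so
  # the reference energy is tightly estimated).
  A <- 2e-6
  f0 <- 750e3
  n <- cfg$sampling_rate * cfg$record_duration
  tt <- (0:(n - 1)) / cfg$sampling_rate
  tone <- A * sin(2 * pi * f0 * tt)
  p_tone <- A^2 / 4 * 5000
  kmin <- ceiling(0.3e6 / 750); kmax <- floor(1.1e6 / 750)
  p_noise_band <- cfg$noise_floor_rms^2 * (kmax - kmin + 1)
  pred <- 10 * log10(1 + p_tone / p_noise_band)
  devs <- vapply(1:100, function(s) {
    rec <- withr::with_seed(s, noise_reference_record(cfg))
    rec$samples <- rec$samples + tone
    attr(rec, "spectrum") <- NULL
    band_snr(averaged_power_spectrum(rec), nspec, "broadband") - pred
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.3)
})

test_that("SNR is invariant under common rescaling of signal and noise", {
  cfg <- tiny_config()
  nref <- withr::with_seed(4, noise_reference_record(cfg))
  rec <- pure_record(cfg, amps(subharmonic = 4e-6, broadband = 3e-6),
                     seed = 9)
  s0 <- band_snr(averaged_power_spectrum(rec),
                 averaged_power_spectrum(nref), "subharmonic")
  rec$samples <- rec$samples * 37
  nref$samples <- nref$samples * 37
  attr(rec, "spectrum") <- NULL
  attr(nref, "spectrum") <- NULL
  s1 <- band_snr(averaged_power_spectrum(rec),
                 averaged_power_spectrum(nref), "subharmonic")
  expect_equal(s0, s1, tolerance = 1e-12)
})

test_that("emission time series has one entry per record and zero dB at reference", {
  cfg <- tiny_config()
  nref <- withr::with_seed(6, noise_reference_record(cfg))
  levels <- emission_time_series(list(nref, nref, nref), nref)
  expect_equal(nrow(levels), 9)          # 3 records x 3 bands
  expect_true(all(levels$snr_db == 0))
  tr <- generate_trial(cfg, 21980, seed = 13)
  lv <- emission_time_series(tr)
  expect_equal(nrow(lv), 3 * nrow(tr$cycles))
  # subharmonic growth: late-exposure SNR exceeds the early post-burst level
  sub <- lv[lv$band == "subharmonic", ]
  post_burst <- sub[sub$time_s >= 15, ]
  if (nrow(post_burst) > 5) {
    expect_gt(mean(tail(post_burst$snr_db, 3)),
              mean(head(post_burst$snr_db, 3)))
  }
})

test_that("bin-estimate variance shrinks as 1/n_segments", {
  fs <- 1e6
  L <- 500
  x <- withr::with_seed(10, rnorm(L * 1000))
  v <- vapply(c(10, 100, 1000), function(ns) {
    ps <- averaged_power_spectrum(x[seq_len(L * ns)], L, fs)
    stats::var(ps$power[2:(L / 2)])      # across-bin spread of a flat spectrum
  }, numeric(1))
  fit <- stats::lm(log(v) ~ log(c(10, 100, 1000)))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("streaming band levels equal the record-wise computation", {
  cfg <- tiny_config(max_cycles = 15)
  sim <- simulate_band_levels(cfg, 21980, seed = 21, trial_id = "trial-21")
  tr <- generate_trial(cfg, 21980, seed = 21, trial_id = "trial-21")
  lv <- emission_time_series(tr)
  expect_equal(dplyr::arrange(sim$levels, time_s, band)$snr_db,
               dplyr::arrange(lv, time_s, band)$snr_db,
               tolerance = 1e-12)
})

test_that("zero-amplitude records measure 0 dB SNR within sampling error", {
  cfg <- desk_config(record_duration = 0.15)   # 112 averaged segments
  ref <- withr::with_seed(61, noise_reference_record(cfg))
  sig <- withr::with_seed(62, noise_reference_record(cfg))
  refs <- averaged_power_spectrum(ref)
  sigs <- averaged_power_spectrum(sig)
  expect_lt(abs(band_snr(sigs, refs, "low_frequency")), 0.5)
  expect_lt(abs(band_snr(sigs, refs, "broadband")), 0.5)
  # the subharmonic band is a single bin, so its ratio estimate is wider
  expect_lt(abs(band_snr(sigs, refs, "subharmonic")), 2)
})
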