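test_that("configuration invariants are enforced", {
  expect_error(synth_config(sampling_rate = 2e6), class = "pcd_config_error")
  expect_error(synth_config(record_duration = 1 / 3),
               class = "pcd_config_error")
  expect_error(synth_config(flow_fluctuation = 0.05),
               class = "pcd_config_error")
  expect_error(synth_config(noise_floor_rms = -1),
               class = "pcd_config_error")
  expect_silent(validate_synth_config(desk_config()))
})

test_that("a noise-only record has the configured RMS", {
  cfg <- desk_config(noise_floor_rms = 0.01)   # 2e5 samples
  rec <- pure_record(cfg, zero_amps)
  expect_equal(sd(rec$samples), 0.01, tolerance = 0.01)
  expect_equal(mean(rec$samples), 0, tolerance = 1e-4)
})

test_that("records and trials are bit-identical under the same seed", {
  cfg <- tiny_config()
  r1 <- withr::with_seed(42, generate_pcd_record(cfg, 3, 21980))
  r2 <- withr::with_seed(42, generate_pcd_record(cfg, 3, 21980))
  expect_identical(r1$samples, r2$samples)
  t1 <- generate_trial(cfg, 21980, seed = 11)
  t2 <- generate_trial(cfg, 21980, seed = 11)
  expect_identical(t1$cycles$record[[3]]$samples,
                   t2$cycles$record[[3]]$samples)
  expect_identical(t1$true_rupture_instant, t2$true_rupture_instant)
  expect_identical(t1$flow_trace$current_ma, t2$flow_trace$current_ma)
})

test_that("band-limited components carry their nominal power", {
  cfg <- desk_config(noise_floor_rms = 0)
  rec <- pure_record(cfg, amps(low_frequency = 3e-6, broadband = 2e-6))
  expect_equal(sd(rec$samples), sqrt(3e-6^2 + 2e-6^2), tolerance = 0.02)
  # doubling a tone amplitude adds 6.02 dB of band power
  nref <- withr::with_seed(5, noise_reference_record(cfg <- desk_config()))
  nspec <- averaged_power_spectrum(nref)
  s1 <- band_snr(averaged_power_spectrum(
    pure_record(cfg, amps(subharmonic = 1e-5), seed = 7)), nspec,
    "subharmonic")
  s2 <- band_snr(averaged_power_spectrum(
    pure_record(cfg, amps(subharmonic = 2e-5), seed = 7)), nspec,
    "subharmonic")
  expect_equal(s2 - s1, 20 * log10(2), tolerance = 0.05)
})

test_that("emission amplitudes are monotone in time and intensity", {
  cfg <- desk_config(burst_enabled = FALSE)
  ts <- seq(0, 200, by = 10)
  for (b in c("low_frequency", "broadband", "subharmonic")) {
    along_t <- vapply(ts, function(t) {
      emission_amplitudes(cfg, t, 21980)[[b]]
    }, numeric(1))
    expect_true(all(diff(along_t) >= 0))
    along_i <- vapply(seq(5000, 24430, by = 1000), function(i) {
      emission_amplitudes(cfg, 50, i)[[b]]
    }, numeric(1))
    expect_true(all(diff(along_i) >= 0))
  }
})

test_that("vessel dose model: trivial limits", {
  cfg <- desk_config()
  st <- withr::with_seed(1, vessel_init(cfg))
  for (i in 1:50) st <- update_vessel(st, zero_amps, cfg)
  expect_false(st$ruptured)
  expect_equal(st$cumulative_dose, 0)
  # constant increment c against threshold tau ruptures at ceiling(tau/c)
  st <- withr::with_seed(1, vessel_init(cfg))
  st$threshold <- 100
  a <- amps(subharmonic = 3e-6)        # rate (3e-6/1e-6)^3 = 27 per second
  k <- 0
  while (!st$ruptured) {
    st <- update_vessel(st, a, cfg)
    k <- k + 1
  }
  expect_equal(k, ceiling(100 / 27))
  expect_equal(st$rupture_instant, k)
})

test_that("simulated rupture times fall in the published range and shift with the hazard", {
  simulate_rupture <- function(cfg, intensity, seed) {
    withr::with_seed(seed, {
      st <- vessel_init(cfg)
      for (t in 0:(cfg$max_cycles - 1)) {
        jit <- rlnorm(3, 0, cfg$amplitude_jitter)
        st <- update_vessel(st, emission_amplitudes(cfg, t, intensity, jit),
                            cfg)
        if (st$ruptured) return(st$rupture_instant)
      }
      NA_real_
    })
  }
  cfg <- desk_config()
  ints <- rep(c(15690, 20570, 21350, 21980, 24430), each = 40)
  rt <- vapply(seq_along(ints), function(i) {
    simulate_rupture(cfg, ints[i], seed = i)
  }, numeric(1))
  rt_obs <- rt[!is.na(rt)]
  qs <- quantile(rt_obs, c(0.25, 0.5, 0.75))
  expect_true(all(qs >= 5 & qs <= 300))
  # lowering the threshold scale shortens the median time to rupture
  cfg_frail <- desk_config(hazard_scale = cfg$hazard_scale - 1)
  rt_frail <- vapply(seq_along(ints), function(i) {
    simulate_rupture(cfg_frail, ints[i], seed = i)
  }, numeric(1))
  expect_lt(median(rt_frail, na.rm = TRUE), qs[[2]])
  # doubling intensity shortens rupture times on paired seeds
  lo <- vapply(1:100, function(s) simulate_rupture(cfg, 12000, s), numeric(1))
  hi <- vapply(1:100, function(s) simulate_rupture(cfg, 24000, s), numeric(1))
  expect_lt(mean(hi, na.rm = TRUE), mean(lo, na.rm = TRUE))
})

test_that("flow traces respect the detection construction", {
  cfg <- desk_config()
  quiet <- withr::with_seed(3, generate_flow_trace(NA, cfg, 120))
  expect_gt(min(quiet$current_ma), 0.97 * cfg$flow_baseline)
  tr <- withr::with_seed(3, generate_flow_trace(42, cfg, 60))
  first_low <- min(tr$time_s[tr$current_ma < 0.97 * cfg$flow_baseline])
  expect_equal(first_low, 50)
  # monotone decline after rupture
  post <- tr$current_ma[tr$time_s >= 42]
  expect_true(all(diff(post) <= 1e-12))
})

test_that("trials terminate correctly and stay consistent with their flow trace", {
  cfg <- tiny_config(hazard_scale = Inf, max_cycles = 25)
  tr <- generate_trial(cfg, rep(21980, 12), seed = 5)
  expect_equal(nrow(tr$cycles), 12)
  expect_true(is.na(tr$true_rupture_instant))
  cfg2 <- tiny_config()
  tr2 <- generate_trial(cfg2, 21980, seed = 8)
  expect_false(is.na(tr2$true_rupture_instant))
  expect_equal(nrow(tr2$cycles), tr2$true_rupture_instant)
  ann <- detect_rupture(tr2$flow_trace)
  expect_equal(ann$rupture_instant, tr2$true_rupture_instant)
})
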