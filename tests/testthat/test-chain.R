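test_that("zero input gives zero output through the whole chain", {
  cfg <- tiny_config(noise_floor_rms = 0)
  rec <- pure_record(cfg, zero_amps)
  env <- analog_chain(rec, chain_config())
  expect_true(all(abs(env) < 1e-14))
})

test_that("an in-band tone demodulates to mean A * gain / pi", {
  cfg <- desk_config(noise_floor_rms = 0)
  A <- 1e-5
  ch <- chain_config()
  rec <- pure_record(cfg, amps(subharmonic = A))
  env <- analog_chain(rec, ch)
  expect_equal(mean(env), A * ch$preamp_gain / pi, tolerance = 0.01)
  # and with the prediction-chain gain of 100
  ch100 <- chain_config(preamp_gain = 100)
  env100 <- analog_chain(rec, ch100)
  expect_equal(mean(env100), A * 100 / pi, tolerance = 0.01)
})

test_that("out-of-band tones are suppressed below 1% of the in-band response", {
  cfg <- desk_config(noise_floor_rms = 0)
  ch <- chain_config()
  n <- cfg$sampling_rate * cfg$record_duration
  tt <- (0:(n - 1)) / cfg$sampling_rate
  oob <- structure(
    list(samples = 1e-5 * sin(2 * pi * 0.5e6 * tt),
         sampling_rate = cfg$sampling_rate, cycle_index = 0,
         trial_id = NA, intensity = 0, amplitudes = NULL),
    class = "pcd_record")
  inband <- pure_record(cfg, amps(subharmonic = 1e-5))
  ratio <- rms_envelope(analog_chain(oob, ch)) /
    rms_envelope(analog_chain(inband, ch))
  expect_lt(ratio, 0.01)
})

test_that("RMS envelope arithmetic", {
  expect_equal(rms_envelope(rep(2.5, 100)), 2.5)
  expect_equal(rms_envelope(c(3, 4)), sqrt(12.5))
  # sinusoidal envelope about a mean: sqrt(m^2 + A^2/2)
  t <- seq(0, 1, length.out = 1e5)
  m <- 2; A <- 0.5
  x <- m + A * sin(2 * pi * 50 * t)
  expect_equal(rms_envelope(x), sqrt(m^2 + A^2 / 2), tolerance = 1e-4)
  expect_error(rms_envelope(numeric(0)), class = "pcd_input_error")
})

test_that("threshold derivation subtracts 1.5 noise units from the corner", {
  # scores arranged so the corner threshold is exactly 0.09
  data <- tibble::tibble(
    rms_v = c(0.02, 0.03, 0.04, 0.05, 0.09, 0.10, 0.11, 0.12),
    class = rep(c("intact_vessel", "pre_rupture"), each = 4)
  )
  out <- derive_threshold(data, noise_rms = 0.02, k = 1.5)
  expect_equal(out$corner_threshold, 0.09)
  expect_equal(out$threshold, 0.06)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  # zero noise leaves the corner threshold untouched
  expect_equal(derive_threshold(data, noise_rms = 0)$threshold, 0.09)
  # adjusted threshold never exceeds the corner threshold
  withr::with_seed(12, {
    for (i in 1:100) {
      d <- tibble::tibble(
        rms_v = c(rnorm(20, 0.05, 0.02), rnorm(8, 0.09, 0.03)),
        class = rep(c("intact_vessel", "pre_rupture"), c(20, 8))
      )
      noise <- runif(1, 0, 0.03)
      res <- derive_threshold(d, noise_rms = noise)
      expect_lte(res$threshold, res$corner_threshold)
      expect_gte(res$threshold, 0)
    }
  })
})

test_that("calibration lookup reproduces tabulated rows and interpolates", {
  look <- calibration_lookup(c(250, 300, 312.5, 325))
  expect_equal(look$power_w, c(20.28, 28.42, (28.42 + 32.06) / 2, 32.06))
  expect_equal(look$isptp_wcm2[1:2], c(15690, 21980))
  expect_equal(look$isptp_wcm2[4], 24430)
  expect_error(calibration_lookup(326), class = "pcd_range_error")
  # power extrapolates as V^2 below the table
  low <- calibration_lookup(125)
  expect_equal(low$power_w, 20.28 / 4)
  # inversion round-trips, and the start intensity maps near 192 mVpp
  v <- voltage_for_intensity(9117)
  expect_equal(v, 192, tolerance = 0.01)
  expect_equal(calibration_lookup(v)$isptp_wcm2, 9117, tolerance = 1e-6)
  expect_equal(voltage_for_intensity(21980), 300)
})

test_that("controller steps follow the flow-chart rules", {
  cfg <- controller_config()
  st <- list(voltage = 250, below_count = 9L, voltage_cap = 300)
  up <- controller_step(st, rms = 0.01, cfg)
  expect_equal(up$voltage, 260)
  expect_equal(up$below_count, 0L)
  expect_equal(up$action, "up")
  down <- controller_step(st, rms = 0.10, cfg)
  expect_equal(down$voltage, 240)
  expect_equal(down$below_count, 0L)
  expect_equal(down$action, "down")
  hold <- controller_step(list(voltage = 250, below_count = 3L,
                               voltage_cap = 300), rms = 0.01, cfg)
  expect_equal(hold$voltage, 250)
  expect_equal(hold$below_count, 4L)
  expect_equal(hold$action, "hold")
  # at the cap a full below-threshold count leaves the voltage unchanged
  capped <- controller_step(list(voltage = 300, below_count = 9L,
                                 voltage_cap = 300), rms = 0.01, cfg)
  expect_equal(capped$voltage, 300)
})

test_that("closed-loop runs respect caps, ramps, and energy arithmetic", {
  synth <- tiny_config(hazard_scale = Inf)
  ctrl <- controller_config(max_cycles = 60)
  ch <- chain_config()
  ina <- run_closed_loop(ctrl, ch, synth, seed = 2, active = FALSE)
  expect_equal(nrow(ina$history), 60)
  expect_false(ina$ruptured)
  expect_true(all(diff(ina$history$isptp_wcm2) >= 0))
  expect_true(all(ina$history$isptp_wcm2 <= 21980 + 1e-9))
  expect_true(all(ina$history$voltage_mvpp >= 0))
  # energy equals the duty-cycled Riemann sum of the power history
  expect_equal(ina$total_energy_j, sum(ina$history$power_w) * 0.5,
               tolerance = 1e-9)
  # constant-power run: start at the cap, 100 cycles of 28.42 W -> 1,421 J
  ctrl2 <- controller_config(start_intensity = 21980, max_cycles = 100)
  const <- run_closed_loop(ctrl2, ch, synth, seed = 3, active = FALSE)
  expect_true(all(const$history$power_w == 28.42))
  expect_equal(const$total_energy_j, 1421)
  expect_equal(const$mean_sptp_intensity, 21980)
  expect_equal(const$time_to_rupture, 100)   # censored at the limit
})

test_that("an infinite threshold makes the active controller a ramp", {
  synth <- tiny_config(hazard_scale = Inf)
  ctrl <- controller_config(threshold = Inf, max_cycles = 40)
  ch <- chain_config()
  act <- run_closed_loop(ctrl, ch, synth, seed = 4, active = TRUE)
  ina <- run_closed_loop(ctrl, ch, synth, seed = 4, active = FALSE)
  expect_identical(act$history$voltage_mvpp, ina$history$voltage_mvpp)
  expect_identical(act$history$rms_v, ina$history$rms_v)
})

test_that("paired active/inactive runs share the same latent vessel", {
  synth <- tiny_config()
  ctrl <- controller_config(max_cycles = 40)
  act <- run_closed_loop(ctrl, chain_config(), synth, seed = 6,
                         active = TRUE)
  ina <- run_closed_loop(ctrl, chain_config(), synth, seed = 6,
                         active = FALSE)
  thr <- function(s) withr::with_seed(s, vessel_init(synth))$threshold
  expect_identical(thr(6), thr(6))
  expect_s3_class(glance(act), "tbl_df")
  expect_s3_class(tidy(ina), "tbl_df")
})

test_that("the controller cuts cavitation dose proportionally more than intensity", {
  synth <- tiny_config(max_cycles = 120)
  ctrl <- controller_config(max_cycles = 120)
  res <- purrr::map_dfr(1:6, function(s) {
    act <- run_closed_loop(ctrl, chain_config(), synth, seed = 100 + s,
                           active = TRUE)
    ina <- run_closed_loop(ctrl, chain_config(), synth, seed = 100 + s,
                           active = FALSE)
    tibble::tibble(
      int_act = act$mean_sptp_intensity, int_ina = ina$mean_sptp_intensity,
      rate_act = act$final_dose / nrow(act$history),
      rate_ina = ina$final_dose / nrow(ina$history))
  })
  intensity_cut <- 1 - mean(res$int_act) / mean(res$int_ina)
  dose_cut <- 1 - mean(res$rate_act) / mean(res$rate_ina)
  expect_gt(dose_cut, intensity_cut)
})
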