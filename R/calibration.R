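#' Drive-voltage calibration table
#'
#' The measured calibration of the HIFU drive chain: function-generator
#' output voltage (mVpp) versus radiation-force-balance acoustic power (W)
#' and the corresponding simulated SPTP focal intensity (W/cm^2) and peak
#' negative pressure (MPa). The six tabulated conditions span
#' 250--325 mVpp; the focal-intensity column is treated as a given
#' calibration (the nonlinear field simulation that produced it is outside
#' this package's scope).
#'
#' @return A tibble: `awg_mvpp`, `power_w`, `isptp_wcm2`, `pneg_mpa`.
#' @examples
#' calibration_table()
#' @export
calibration_table <- function() {
  load_table_fixture("calibration")
}

#' Map drive voltage to acoustic power and focal intensity
#'
#' Within the tabulated voltage range, acoustic power and SPTP intensity
#' are piecewise-linearly interpolated in voltage. Below the lowest
#' tabulated voltage, power extrapolates as voltage squared (electrical
#' power scaling) anchored at the lowest row, and intensity follows the
#' first tabulated intensity-versus-power slope (floored at zero). Voltages
#' above the table maximum are a range error: the calibration does not
#' extend there.
#'
#' @param awg_voltage Drive voltage(s), mVpp.
#' @param table Calibration tibble, by default [calibration_table()].
#' @return A tibble with one row per voltage: `awg_mvpp`, `power_w`,
#'   `isptp_wcm2`.
#' @examples
#' calibration_lookup(c(250, 300, 312.5))
#' @export
calibration_lookup <- function(awg_voltage, table = calibration_table()) {
  v <- table$awg_mvpp
  if (any(awg_voltage > max(v) + 1e-9)) {
    abort(sprintf("voltage above the calibrated maximum (%g mVpp)", max(v)),
          class = "pcd_range_error")
  }
  if (any(awg_voltage < 0)) {
    abort("voltage must be non-negative", class = "pcd_range_error")
  }
  slope <- (table$isptp_wcm2[2] - table$isptp_wcm2[1]) /
    (table$power_w[2] - table$power_w[1])
  one <- function(vq) {
    if (vq >= v[1]) {
      p <- approx(v, table$power_w, xout = vq)$y
      i <- approx(v, table$isptp_wcm2, xout = vq)$y
    } else {
      p <- table$power_w[1] * (vq / v[1])^2
      i <- max(0, table$isptp_wcm2[1] - slope * (table$power_w[1] - p))
    }
    c(p, i)
  }
  res <- vapply(awg_voltage, one, numeric(2))
  tibble(awg_mvpp = awg_voltage, power_w = res[1, ], isptp_wcm2 = res[2, ])
}

#' Invert the calibration: voltage delivering a target intensity
#'
#' @param intensity Target SPTP intensity, W/cm^2 (at most the calibrated
#'   maximum).
#' @param table Calibration tibble.
#' @return Drive voltage, mVpp.
#' @examples
#' voltage_for_intensity(9117)    # controller start level, about 192 mVpp
#' @export
voltage_for_intensity <- function(intensity, table = calibration_table()) {
  if (intensity > max(table$isptp_wcm2) + 1e-9) {
    abort("intensity above the calibrated maximum", class = "pcd_range_error")
  }
  if (intensity >= table$isptp_wcm2[1]) {
    return(approx(table$isptp_wcm2, table$awg_mvpp, xout = intensity,
                  ties = "ordered")$y)
  }
  slope <- (table$isptp_wcm2[2] - table$isptp_wcm2[1]) /
    (table$power_w[2] - table$power_w[1])
  p <- table$power_w[1] - (table$isptp_wcm2[1] - intensity) / slope
  if (p <= 0) {
    abort("intensity below the invertible calibration range",
          class = "pcd_range_error")
  }
  table$awg_mvpp[1] * sqrt(p / table$power_w[1])
}
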