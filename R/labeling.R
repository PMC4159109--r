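#' Detect vessel rupture from a flow-meter trace
#'
#' Detectable rupture is a drop of `drop_fraction` (3%) of the flow-meter
#' output current below baseline; because the meter responds with a
#' measured delay, the rupture instant is defined as `lag` (8 s) before the
#' detection sample. Baseline is the mean of the pre-sonication samples
#' (times before `sonication_start`); if none exist, the first sample.
#'
#' @param trace A flow trace tibble with columns `time_s`, `current_ma`
#'   (1-s grid). The sonication start time is read from the
#'   `sonication_start` attribute (default 0).
#' @param drop_fraction Fractional current drop defining detection.
#' @param lag Meter response delay, s.
#' @return A `rupture_annotation`: list with `detection_time`,
#'   `rupture_instant` (both `NA` when no drop occurs), `baseline_current`.
#' @examples
#' tr <- withr::with_seed(1, generate_flow_trace(42, desk_config(), 60))
#' detect_rupture(tr)$rupture_instant
#' @export
detect_rupture <- function(trace, drop_fraction = 0.03, lag = 8) {
  if (nrow(trace) == 0) {
    abort("empty flow trace", class = "pcd_input_error")
  }
  start <- attr(trace, "sonication_start") %||% 0
  pre <- trace$current_ma[trace$time_s < start]
  baseline <- if (length(pre) > 0) mean(pre) else trace$current_ma[1]
  if (baseline <= 0) {
    abort("flow baseline is zero; cannot detect a fractional drop",
          class = "pcd_input_error")
  }
  below <- which(trace$current_ma < (1 - drop_fraction) * baseline &
                   trace$time_s >= start)
  detection <- if (length(below) > 0) trace$time_s[below[1]] else NA_real_
  structure(
    list(detection_time = detection,
         rupture_instant = if (is.na(detection)) NA_real_ else detection - lag,
         baseline_current = baseline),
    class = "rupture_annotation")
}

#' @export
print.rupture_annotation <- function(x, ...) {
  if (is.na(x$detection_time)) {
    cat("<rupture_annotation> no rupture detected\n")
  } else {
    cat(sprintf("<rupture_annotation> detected %g s, rupture instant %g s\n",
                x$detection_time, x$rupture_instant))
  }
  invisible(x)
}

#' Label per-cycle emissions relative to the rupture instant
#'
#' Partitions on-cycle emissions into the classes used for rupture
#' prediction: `pre_rupture` for cycles within `window` seconds before the
#' rupture instant (`rupture_instant - window <= t < rupture_instant`),
#' `intact_vessel` for earlier cycles and for every cycle of a non-rupture
#' trial, and `excluded` for cycles at or after the rupture instant (the
#' analysis stops at rupture).
#'
#' @param levels A `band_levels` tibble (or any tibble with a `time_s`
#'   column) for one trial.
#' @param annotation A `rupture_annotation` from [detect_rupture()] (or a
#'   number / `NA` taken directly as the rupture instant).
#' @param window Pre-rupture window length, s (>= 1). The primary analysis
#'   uses 10 s; [window_sweep()] varies it.
#' @return The input tibble with an added factor column `class`.
#' @examples
#' lv <- tibble::tibble(time_s = 0:49)
#' table(label_emissions(lv, 42)$class)
#' @export
label_emissions <- function(levels, annotation, window = 10) {
  stopifnot(window >= 1)
  rupture <- if (inherits(annotation, "rupture_annotation")) {
    annotation$rupture_instant
  } else {
    annotation
  }
  t <- levels$time_s
  cls <- if (is.na(rupture)) {
    rep("intact_vessel", length(t))
  } else {
    dplyr::case_when(
      t >= rupture ~ "excluded",
      t >= rupture - window ~ "pre_rupture",
      TRUE ~ "intact_vessel"
    )
  }
  levels$class <- factor(cls,
                         levels = c("pre_rupture", "intact_vessel", "excluded"))
  levels
}
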