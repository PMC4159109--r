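#' ROC curve and AUROC for rupture prediction
#'
#' Builds the receiver operating characteristic of a continuous emission
#' score for classifying pre-rupture versus intact-vessel cycles, using the
#' decision rule "score >= threshold => positive" at every unique observed
#' score. The area under the curve is computed by the rank (Mann-Whitney)
#' identity, which equals the trapezoidal area over the operating points
#' and is the probability that a random positive outscores a random
#' negative (ties counted half). Its standard error uses the Hanley-McNeil
#' formula, and a normal test against the chance value 0.5 yields the
#' p-value and 95% confidence interval.
#'
#' @param data A data frame with score and class columns (e.g. labeled
#'   [emission_time_series()] output), or `NULL` when `scores` and `labels`
#'   are passed directly.
#' @param score,truth Tidy-selected columns of `data`: the numeric score
#'   and the class column.
#' @param positive Level of `truth` treated as positive
#'   (default `"pre_rupture"`). Rows with class `"excluded"` are dropped;
#'   all remaining non-positive rows are negatives.
#' @param scores,labels Directly supplied numeric scores and logical (or
#'   two-level) labels, as an alternative to `data`.
#' @return A `pcd_roc`: list with `points` (tibble: `threshold`,
#'   `sensitivity`, `specificity`), `auroc`, `auroc_se`, `p_value`,
#'   `ci_low`, `ci_high`, `n_positive`, `n_negative`, plus the scores and
#'   labels used.
#' @examples
#' roc <- roc_curve(scores = c(1, 2, 3, 4),
#'                  labels = c(FALSE, FALSE, TRUE, TRUE))
#' roc$auroc
#' @export
roc_curve <- function(data = NULL, score = NULL, truth = NULL,
                      positive = "pre_rupture",
                      scores = NULL, labels = NULL) {
  if (!is.null(data)) {
    scores <- eval_tidy(enquo(score), data)
    cls <- eval_tidy(enquo(truth), data)
    keep <- cls != "excluded"
    scores <- scores[keep]
    labels <- cls[keep] == positive
  } else {
    labels <- as.logical(labels)
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to build an ROC curve",
          class = "pcd_input_error")
  }
  # operating points at every unique threshold, rule: score >= threshold
  thr <- sort(unique(scores))
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  tp_cum <- cumsum(labels[ord])
  fp_cum <- cumsum(!labels[ord])
  # number of scores >= each threshold indexes the cumulative counts
  idx <- length(s_sorted) -
    findInterval(thr, rev(s_sorted), left.open = TRUE)
  sens <- tp_cum[idx] / n_pos
  spec <- 1 - fp_cum[idx] / n_neg
  points <- tibble(
    threshold = c(thr, Inf),
    sensitivity = c(sens, 0),
    specificity = c(spec, 1)
  )
  # AUROC via the rank identity (handles ties exactly)
  r <- rank(scores)
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auroc / (2 - auroc)
  q2 <- 2 * auroc^2 / (1 + auroc)
  se <- sqrt((auroc * (1 - auroc) + (n_pos - 1) * (q1 - auroc^2) +
                (n_neg - 1) * (q2 - auroc^2)) / (n_pos * n_neg))
  z <- if (se > 0) (auroc - 0.5) / se else Inf * sign(auroc - 0.5)
  structure(
    list(points = points,
         auroc = auroc,
         auroc_se = se,
         p_value = 2 * pnorm(-abs(z)),
         ci_low = max(0, auroc - qnorm(0.975) * se),
         ci_high = min(1, auroc + qnorm(0.975) * se),
         n_positive = n_pos,
         n_negative = n_neg,
         scores = scores,
         labels = labels),
    class = "pcd_roc")
}

#' @export
print.pcd_roc <- function(x, ...) {
  cat(sprintf("<pcd_roc> AUROC %.3f (SE %.3f, p %.3g), %d pos / %d neg\n",
              x$auroc, x$auroc_se, x$p_value, x$n_positive, x$n_negative))
  invisible(x)
}

#' @describeIn roc_curve Operating points as a tibble.
#' @param x A `pcd_roc`.
#' @param ... Unused.
#' @method tidy pcd_roc
#' @export
tidy.pcd_roc <- function(x, ...) x$points

#' @describeIn roc_curve One-row AUROC summary.
#' @method glance pcd_roc
#' @export
glance.pcd_roc <- function(x, ...) {
  tibble(auroc = x$auroc, auroc_se = x$auroc_se, p_value = x$p_value,
         ci_low = x$ci_low, ci_high = x$ci_high,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @describeIn roc_curve ROC curve plot (TPR vs FPR).
#' @param object A `pcd_roc`.
#' @method autoplot pcd_roc
#' @export
autoplot.pcd_roc <- function(object, ...) {
  pts <- object$points |>
    dplyr::arrange(dplyr::desc(.data$threshold))
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("AUROC %.3f", object$auroc))
}

#' Corner operating point and its accuracy metrics
#'
#' Selects the ROC operating point simultaneously maximizing sensitivity
#' and specificity, i.e. the threshold whose point is closest (Euclidean
#' distance) to the perfect-classifier corner (FPR, TPR) = (0, 1), ties
#' broken toward the lower threshold. Positive and negative predictive
#' values come from the confusion matrix at that threshold on the provided
#' sample.
#'
#' @param roc A `pcd_roc` from [roc_curve()].
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @examples
#' roc <- roc_curve(scores = c(1, 2, 3, 4),
#'                  labels = c(FALSE, FALSE, TRUE, TRUE))
#' corner_threshold(roc)
#' @export
corner_threshold <- function(roc) {
  pts <- roc$points
  d2 <- (1 - pts$specificity)^2 + (1 - pts$sensitivity)^2
  best <- which(d2 == min(d2))
  i <- best[which.min(pts$threshold[best])]
  thr <- pts$threshold[i]
  pos_call <- roc$scores >= thr
  tp <- sum(pos_call & roc$labels)
  fp <- sum(pos_call & !roc$labels)
  fn <- sum(!pos_call & roc$labels)
  tn <- sum(!pos_call & !roc$labels)
  tibble(
    threshold = thr,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' AUROC as a function of the pre-rupture window length
#'
#' Relabels each trial's emissions at every candidate window length and
#' recomputes the AUROC of the selected band, quantifying how strongly
#' prediction performance depends on the definition of "pre-rupture".
#'
#' @param levels A `band_levels` tibble covering one or more trials
#'   (column `trial_id`).
#' @param annotations A tibble with columns `trial_id`, `rupture_instant`
#'   (`NA` for non-rupture trials).
#' @param windows Window lengths to evaluate, s.
#' @param band Which emission band's SNR to score (default subharmonic).
#' @return A tibble: `window_s`, `auroc`, `n_positive`, `n_negative`.
#' @export
window_sweep <- function(levels, annotations, windows = 1:20,
                         band = "subharmonic") {
  lv <- levels[levels$band == band, ]
  if (nrow(lv) == 0) {
    abort("no rows for the requested band", class = "pcd_input_error")
  }
  by_trial <- split(lv, lv$trial_id)
  rupture_of <- stats::setNames(annotations$rupture_instant,
                                annotations$trial_id)
  if (!all(names(by_trial) %in% names(rupture_of))) {
    abort("annotations missing for some trials", class = "pcd_input_error")
  }
  purrr::map_dfr(windows, function(w) {
    labeled <- purrr::map_dfr(names(by_trial), function(id) {
      label_emissions(by_trial[[id]], rupture_of[[id]], window = w)
    })
    roc <- roc_curve(labeled, score = snr_db, truth = class)
    tibble(window_s = w, auroc = roc$auroc,
           n_positive = roc$n_positive, n_negative = roc$n_negative)
  })
}
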