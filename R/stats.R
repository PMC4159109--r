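#' Descriptive summary of rupture times (or any sample)
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator), and
#' range.
#'
#' @param values Numeric vector (NA dropped).
#' @return One-row tibble: `n`, `mean`, `sd`, `min`, `max`.
#' @examples
#' t1 <- load_table_fixture("table1")
#' descriptive_stats(t1$time_to_rupture_s)
#' @export
descriptive_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("no non-missing values", class = "pcd_input_error")
  }
  tibble(n = length(values), mean = mean(values),
         sd = if (length(values) > 1) sd(values) else NA_real_,
         min = min(values), max = max(values))
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation with the exact t-based two-sided test
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param data Optional data frame containing the two columns.
#' @param x,y Tidy-selected columns of `data`, or numeric vectors when
#'   `data` is `NULL`.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    x <- eval_tidy(enquo(x), data)
    y <- eval_tidy(enquo(y), data)
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need n >= 3", class = "pcd_input_error")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Paired Wilcoxon signed-rank test with Pratt zero handling
#'
#' Tests whether `b` systematically exceeds `a` (one-sided by default)
#' using the signed-rank statistic with the Pratt convention for zero
#' differences: zeros participate in the joint ranking of |differences|
#' (ties receive mean ranks) but are dropped from both rank sums, so
#' `T-` is the rank sum of the negative differences among all `N` pairs.
#'
#' The exact p-value is taken from the classical signed-rank null
#' distribution -- sign assignments over integer ranks `1..N` with `N` the
#' total number of pairs -- evaluated as `P(T- <= observed)` for the
#' one-sided alternative `b > a` (and symmetrically for the others). For
#' `N > 15` a normal approximation with continuity correction is used.
#'
#' @param a,b Paired samples (e.g. controller-inactive and
#'   controller-active rupture times, censored values entered at the
#'   censoring limit).
#' @param alternative `"greater"` (b > a), `"less"`, or `"two.sided"`.
#' @param exact_limit Largest `N` for which the exact null is enumerated.
#' @return One-row tibble: `t_minus`, `t_plus`, `n`, `p_value`, `method`.
#' @examples
#' t4 <- load_table_fixture("table4")
#' wilcoxon_signed_rank(t4$time_inactive_s, t4$time_active_s)
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("greater", "less",
                                                       "two.sided"),
                                 exact_limit = 15) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) abort("need at least 2 pairs", class = "pcd_input_error")
  if (all(d == 0)) {
    abort("all differences are zero", class = "pcd_input_error")
  }
  r <- rank(abs(d))                      # zeros included in the ranking
  t_minus <- sum(r[d < 0])
  t_plus <- sum(r[d > 0])
  cdf_leq <- function(q) {
    # P(T <= q) under signs on ranks 1..n, by convolution
    if (q < 0) return(0)
    counts <- c(1, rep(0, n * (n + 1) / 2))
    for (rk in seq_len(n)) {
      shifted <- c(rep(0, rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    sum(counts[seq_len(floor(q) + 1)]) / 2^n
  }
  if (n <= exact_limit) {
    method <- "exact"
    p <- switch(alternative,
      greater = cdf_leq(t_minus),
      less = cdf_leq(t_plus),
      two.sided = min(1, 2 * cdf_leq(min(t_minus, t_plus))))
  } else {
    method <- "normal approximation"
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- function(t) (t - mu + 0.5) / sigma
    p <- switch(alternative,
      greater = pnorm(z(t_minus)),
      less = pnorm(z(t_plus)),
      two.sided = min(1, 2 * pnorm(z(min(t_minus, t_plus)))))
  }
  tibble(t_minus = t_minus, t_plus = t_plus, n = n, p_value = p,
         method = method)
}

#' Pooled-variance independent-sample t test
#'
#' Two-sample Student t test with the equal-variance assumption (two-sided
#' by default), as used to compare emission levels between classes and
#' rupture-delay differences between vessel types.
#'
#' @param a,b The two groups.
#' @param alternative Test sidedness.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
t_test_pooled <- function(a, b, alternative = "two.sided") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs n >= 2", class = "pcd_input_error")
  }
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(tibble(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE, alternative = alternative)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' One-sided paired t test
#'
#' Tests whether `b` exceeds `a` on average (alternative `b - a > 0`), as
#' used for trial-mean focal intensity and total delivered energy in
#' paired controller-active versus controller-inactive trials.
#'
#' @param a,b Paired samples.
#' @param alternative Test sidedness (default `"greater"`: b > a).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_difference`.
#' @export
t_test_paired <- function(a, b, alternative = "greater") {
  stopifnot(length(a) == length(b))
  d <- b - a
  if (sd(d) == 0) {
    return(tibble(t = 0, df = length(d) - 1,
                  p_value = if (alternative == "two.sided") 1 else 0.5,
                  mean_difference = mean(d)))
  }
  tt <- t.test(b, a, paired = TRUE, alternative = alternative)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_difference = mean(d))
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Hypergeometric exact test; the two-sided p-value sums all tables with
#' probability not exceeding the observed one (the base R convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative Test sidedness.
#' @return One-row tibble: `p_value`, `odds_ratio`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 0, 6), nrow = 2))
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("need a 2x2 table of non-negative counts",
          class = "pcd_input_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("table has a zero margin", class = "pcd_input_error")
  }
  ft <- fisher.test(table, alternative = alternative)
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Exposure summary: mean intensity and total delivered energy
#'
#' Mean SPTP focal intensity over the delivered cycles and total acoustic
#' energy under the pulsed protocol (`energy = sum(power) * duty *
#' pulse_period`, with 0.5-s on-time per 1-s cycle by default).
#'
#' @param history Data frame with per-cycle `power_w` and `isptp_wcm2`
#'   columns (e.g. a [run_closed_loop()] history).
#' @param duty On fraction of each pulse period.
#' @param pulse_period Pulse period, s.
#' @return One-row tibble: `n_cycles`, `mean_sptp_intensity`,
#'   `total_energy_j`.
#' @examples
#' exposure_summary(tibble::tibble(power_w = rep(28.42, 100),
#'                                 isptp_wcm2 = rep(21980, 100)))
#' @export
exposure_summary <- function(history, duty = 0.5, pulse_period = 1) {
  if (nrow(history) == 0) {
    abort("empty exposure history", class = "pcd_input_error")
  }
  tibble(n_cycles = nrow(history),
         mean_sptp_intensity = mean(history$isptp_wcm2),
         total_energy_j = sum(history$power_w) * duty * pulse_period)
}
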