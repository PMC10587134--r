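# Effect sizes, confidence intervals and t statistics computed from group
# summaries (mean, SD, n) of per-participant RT-CIT effects.

effect_estimate <- function(point, ci_low, ci_high, label) {
  if (!(ci_low <= point && point <= ci_high)) {
    abort_data("confidence interval does not bracket the point estimate")
  }
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 label = label), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %s [%s; %s]\n", x$label, fmt2(x$point), fmt2(x$ci_low),
              fmt2(x$ci_high)))
  invisible(x)
}

check_group <- function(mean, sd, n, what = "group") {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0 || n < 2) {
    abort_data(sprintf("%s summary needs finite mean, sd >= 0 and n >= 2",
                       what))
  }
}

crit_value <- function(critical, level, df) {
  a <- (1 - level) / 2
  switch(match.arg(critical, c("z", "t")),
         z = stats::qnorm(1 - a),
         t = stats::qt(1 - a, df))
}

#' Within-condition standardised effect (Cohen's d) with CI
#'
#' For a one-sample contrast against zero, d = mean / sd of the
#' per-participant effects. The 95% CI uses the large-sample approximation
#' d +/- crit * sqrt(1/n + d^2 / (2n)). `critical = "z"` (the default) uses
#' the normal critical value, which reproduces conventionally reported
#' summary-table CIs; `"t"` uses the t(n-1) quantile.
#'
#' @param mean,sd,n Group summary of the per-participant effects.
#' @param level Confidence level.
#' @param critical `"z"` or `"t"`.
#' @return An `effect_estimate` with label `"within_d"`.
#' @export
#' @examples
#' cohens_d_within(35.84, 34.14, 131)  # 1.05 [0.84; 1.26]
cohens_d_within <- function(mean, sd, n, level = 0.95, critical = "z") {
  check_group(mean, sd, n)
  if (sd == 0) abort_data("sd = 0: standardised effect undefined")
  d <- mean / sd
  se <- sqrt(1 / n + d^2 / (2 * n))
  crit <- crit_value(critical, level, n - 1)
  effect_estimate(d, d - crit * se, d + crit * se, "within_d")
}

#' Mean effect with CI from a group summary
#'
#' CI = mean +/- crit * sd / sqrt(n), with a normal critical value by default
#' (`critical = "t"` for the t-based interval).
#'
#' @inheritParams cohens_d_within
#' @return An `effect_estimate` with label `"mean_difference"`.
#' @export
#' @examples
#' mean_effect_ci(23.40, 32.04, 161)  # 23.40 [18.45; 28.35]
mean_effect_ci <- function(mean, sd, n, level = 0.95, critical = "z") {
  check_group(mean, sd, n)
  crit <- crit_value(critical, level, n - 1)
  half <- crit * sd / sqrt(n)
  effect_estimate(mean, mean - half, mean + half, "mean_difference")
}

#' Between-condition contrast from group summaries
#'
#' Independent-samples comparison of two groups of per-participant effects:
#' pooled-variance Student's t (the frequentist companion of the default
#' Bayesian independent-samples t test), two-sided p, the mean difference with
#' its CI, and the between-groups standardised difference
#' d = difference / pooled SD. `welch = TRUE` switches to the
#' Welch-Satterthwaite t (d is then standardised by the root mean of the two
#' variances).
#'
#' @param mean1,sd1,n1 Summary of the first group.
#' @param mean2,sd2,n2 Summary of the second group.
#' @param welch Use the Welch test instead of pooled variance.
#' @param level Confidence level for the difference CI.
#' @param critical `"z"` (default) or `"t"` critical value for the CI.
#' @return List with `difference`, `ci_low`, `ci_high`, `sd_pooled`, `t`,
#'   `df`, `p`, `d`.
#' @export
#' @examples
#' two_sample_contrast(35.84, 34.14, 131, 23.40, 32.04, 161)
two_sample_contrast <- function(mean1, sd1, n1, mean2, sd2, n2,
                                welch = FALSE, level = 0.95, critical = "z") {
  check_group(mean1, sd1, n1, "first group")
  check_group(mean2, sd2, n2, "second group")
  if (n1 + n2 < 4) abort_data("need at least 4 observations in total")
  diff <- mean1 - mean2
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    sd_std <- sqrt((sd1^2 + sd2^2) / 2)
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    sd_std <- sqrt(sp2)
  }
  if (se == 0) abort_data("zero standard error: groups are degenerate")
  t <- diff / se
  crit <- crit_value(critical, level, df)
  list(difference = diff, ci_low = diff - crit * se,
       ci_high = diff + crit * se, sd_pooled = sd_std, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df), d = diff / sd_std)
}

#' Group summary of a raw effect vector
#'
#' Convenience bridge from per-participant effect vectors to the
#' summary-based estimators.
#'
#' @param x Numeric vector of per-participant effects.
#' @return List with `mean`, `sd`, `n`.
#' @export
group_summary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) abort_data("need at least 2 finite effects")
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}
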