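# Detection-efficiency analysis: a simulated naive (unknowledgeable) null for
# the dCIT score, nonparametric AUC, a bootstrap with percentile CI, and the
# Hanley-McNeil comparison of two independent AUCs.
#
# Knowledgeable participants are observed; naive ones are simulated under the
# assumption that probes carry no special meaning for them, so their dCIT has
# mean 0 and an SD given by the sampling variance of a standardised mean
# difference at true effect size delta:
#   Var(dCIT) = (N-1)/(N-3) * (4/N) * (1 + delta^2/8).

#' Null standard deviation of dCIT for naive participants
#'
#' Square root of the variance approximation above. The expression itself is
#' a variance; `literal = TRUE` returns it un-rooted for sensitivity analysis
#' against the literal reading of the formula as an SD.
#'
#' @param n Sample size entering the variance formula (the per-condition
#'   number of knowledgeable participants); must exceed 3.
#' @param delta True population effect size of the simulated group (0 for
#'   naive participants).
#' @param literal Return the raw expression instead of its square root.
#' @return The null SD (or raw expression) of dCIT.
#' @export
#' @examples
#' naive_sd(131)  # ~0.176
naive_sd <- function(n, delta = 0, literal = FALSE) {
  if (n <= 3) abort_config("the naive-null variance formula requires n > 3")
  v <- (n - 1) / (n - 3) * (4 / n) * (1 + delta^2 / 8)
  if (literal) v else sqrt(v)
}

#' Specification of the simulated naive null
#'
#' @inheritParams naive_sd
#' @return List of class `naive_null_spec` with `n`, `delta`, `sd`.
#' @export
naive_null_spec <- function(n, delta = 0, literal = FALSE) {
  structure(list(n = n, delta = delta,
                 sd = naive_sd(n, delta, literal = literal)),
            class = "naive_null_spec")
}

#' Draw simulated naive dCIT scores
#'
#' Naive dCITs are modelled as Normal(0, `spec$sd`).
#'
#' @param spec A [naive_null_spec()].
#' @param n_draws Number of scores to draw.
#' @param seed Optional seed; if `NULL` the current RNG stream is consumed.
#' @return Numeric vector of length `n_draws`.
#' @export
simulate_naive <- function(spec, n_draws, seed = NULL) {
  if (!inherits(spec, "naive_null_spec")) {
    abort_config("spec must be a naive_null_spec")
  }
  if (n_draws < 1) abort_config("n_draws must be >= 1")
  with_seed(seed, stats::rnorm(n_draws, 0, spec$sd))
}

#' Nonparametric AUC (Mann-Whitney estimator)
#'
#' The probability that a randomly drawn knowledgeable score exceeds a
#' randomly drawn naive score, with ties counted 1/2 — i.e. the normalised
#' Mann-Whitney U, computed via midranks.
#'
#' @param knowledgeable_scores,naive_scores Non-empty numeric score vectors;
#'   higher scores indicate more evidence of concealed knowledge.
#' @return A value in [0, 1].
#' @export
#' @examples
#' auc(c(0.5, 0.2), c(0.1, 0.3))  # 0.75
auc <- function(knowledgeable_scores, naive_scores) {
  n_pos <- length(knowledgeable_scores)
  n_neg <- length(naive_scores)
  if (!n_pos || !n_neg) abort_data("both score samples must be non-empty")
  if (anyNA(knowledgeable_scores) || anyNA(naive_scores)) {
    abort_data("scores must not contain NA")
  }
  r <- rank(c(knowledgeable_scores, naive_scores))
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Bootstrapped detection efficiency
#'
#' Repeats the simulated-naive detection analysis `n_boot` times: each
#' replicate draws a fresh naive sample of size `spec$n` from the null and
#' (under the default `scheme = "resample"`) also resamples the knowledgeable
#' dCITs with replacement, then computes [auc()]. The point estimate is the
#' mean replicate AUC; the CI is the 2.5/97.5 percentile interval of the
#' replicates (`ci = "normal"` for mean +/- 1.96 * SD instead).
#' `scheme = "naive_only"` keeps the observed knowledgeable sample fixed and
#' redraws only the simulated naive group.
#'
#' @param knowledgeable_dcits Observed dCIT scores (>= 2).
#' @param spec A [naive_null_spec()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional RNG seed.
#' @param scheme `"resample"` or `"naive_only"`.
#' @param ci `"percentile"` or `"normal"`.
#' @return A list of class `auc_result`: `mean_auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `replicates`, `scheme`, `ci_method`, `spec`, `seed`.
#' @export
bootstrap_auc <- function(knowledgeable_dcits, spec, n_boot = 100L,
                          seed = NULL, scheme = c("resample", "naive_only"),
                          ci = c("percentile", "normal")) {
  scheme <- match.arg(scheme)
  ci <- match.arg(ci)
  if (length(knowledgeable_dcits) < 2) {
    abort_data("need at least 2 knowledgeable scores")
  }
  if (!inherits(spec, "naive_null_spec")) {
    abort_config("spec must be a naive_null_spec")
  }
  if (n_boot < 1) abort_config("n_boot must be >= 1")
  n_boot <- as.integer(n_boot)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    pos <- if (scheme == "resample") {
      sample(knowledgeable_dcits, replace = TRUE)
    } else knowledgeable_dcits
    auc(pos, simulate_naive(spec, spec$n))
  }, numeric(1)))
  bounds <- if (ci == "percentile") {
    unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  } else {
    mean(reps) + c(-1, 1) * stats::qnorm(0.975) * stats::sd(reps)
  }
  structure(list(mean_auc = mean(reps),
                 ci_low = max(min(bounds[1], mean(reps)), 0),
                 ci_high = min(max(bounds[2], mean(reps)), 1),
                 n_boot = n_boot, replicates = reps, scheme = scheme,
                 ci_method = ci, spec = spec, seed = seed),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrapped AUC: %.3f [%.3f; %.3f] (%d replicates, %s scheme, naive n = %d, null SD = %.4f)\n",
    x$mean_auc, x$ci_low, x$ci_high, x$n_boot, x$scheme, x$spec$n, x$spec$sd))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' The classic (1982) approximation for an empirical AUC A from independent
#' positive and negative samples:
#' SE^2 = [A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)] /
#' (n_pos * n_neg), with Q1 = A/(2-A) and Q2 = 2A^2/(1+A).
#'
#' @param auc AUC estimate in (0, 1); values exactly 0 or 1 give a degenerate
#'   SE and raise a warning.
#' @param n_pos,n_neg Group sizes (>= 2).
#' @return The standard error.
#' @export
#' @examples
#' hanley_mcneil_se(0.84, 131, 131)  # ~0.0248
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (auc < 0 || auc > 1) abort_data("auc must lie in [0, 1]")
  if (n_pos < 2 || n_neg < 2) abort_data("group sizes must be >= 2")
  if (auc == 0 || auc == 1) {
    warning("AUC at the boundary: Hanley-McNeil SE is degenerate")
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Compare two independent AUCs
#'
#' Z test for the difference of two AUCs estimated on independent samples:
#' Z = (auc1 - auc2) / sqrt(SE1^2 + SE2^2), with Hanley-McNeil SEs unless
#' standard errors (e.g. bootstrap SDs) are supplied.
#'
#' @param auc1,auc2 The two AUC estimates.
#' @param n1_pos,n1_neg,n2_pos,n2_neg Group sizes behind each AUC.
#' @param se1,se2 Optional externally supplied standard errors.
#' @return List with `z`, `p` (two-sided), `se1`, `se2`.
#' @export
compare_aucs <- function(auc1, n1_pos, n1_neg, auc2, n2_pos, n2_neg,
                         se1 = NULL, se2 = NULL) {
  if (is.null(se1)) se1 <- hanley_mcneil_se(auc1, n1_pos, n1_neg)
  if (is.null(se2)) se2 <- hanley_mcneil_se(auc2, n2_pos, n2_neg)
  if (se1 == 0 && se2 == 0) {
    abort_data("both standard errors are zero: Z undefined")
  }
  z <- (auc1 - auc2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), se1 = se1, se2 = se2)
}

#' ROC curve points
#'
#' Empirical ROC of knowledgeable versus naive scores: for every threshold
#' (each distinct observed score, scanned from high to low with the
#' classify-if-score >= threshold rule), the true- and false-positive rates.
#'
#' @inheritParams auc
#' @return Data frame with `threshold`, `tpr`, `fpr`, starting at (0, 0) and
#'   ending at (1, 1).
#' @export
roc_points <- function(knowledgeable_scores, naive_scores) {
  if (!length(knowledgeable_scores) || !length(naive_scores)) {
    abort_data("both score samples must be non-empty")
  }
  thr <- sort(unique(c(knowledgeable_scores, naive_scores)),
              decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(knowledgeable_scores >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(naive_scores >= s), numeric(1))
  data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}
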