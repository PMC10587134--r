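# The preregistered sequential Bayes-factor sampling plan: recruit in batches,
# recompute the between-condition BF10 after each batch, stop on substantial
# evidence for either hypothesis or at a maximum sample size.

#' Sequential sampling plan
#'
#' Batch-wise Bayes-factor stopping rule: after each completed batch of
#' `batch_size` participants the between-condition BF10 is computed; sampling
#' stops with support for H1 when BF10 > `bf_upper`, with support for H0 when
#' BF10 < `bf_lower`, and is declared inconclusive once `n_max` participants
#' (before exclusions) have been tested. Defaults are the preregistered
#' thresholds.
#'
#' @param bf_upper Upper BF10 threshold (> 1).
#' @param bf_lower Lower BF10 threshold (in (0, 1)).
#' @param batch_size Participants recruited per batch.
#' @param n_max Maximum total recruitment.
#' @return A list of class `sequential_plan`.
#' @export
sequential_plan <- function(bf_upper = 5, bf_lower = 0.2, batch_size = 100L,
                            n_max = 300L) {
  if (!(bf_lower > 0 && bf_lower < 1 && bf_upper > 1)) {
    abort_config("need 0 < bf_lower < 1 < bf_upper")
  }
  if (batch_size < 1 || n_max < 1) {
    abort_config("batch_size and n_max must be positive")
  }
  structure(list(bf_upper = bf_upper, bf_lower = bf_lower,
                 batch_size = as.integer(batch_size),
                 n_max = as.integer(n_max)),
            class = "sequential_plan")
}

#' Apply the sequential stopping rule to a BF trajectory
#'
#' Scans the per-batch BF10 values in order and stops at the first crossing of
#' either threshold. A trajectory that never crosses is `inconclusive_max_n`
#' once the cumulative recruitment reaches `plan$n_max`, and `continue`
#' (sampling not yet resolved) if it ends earlier.
#'
#' @param bf_trajectory Numeric vector, one BF10 per completed batch
#'   (cumulative analyses).
#' @param plan A [sequential_plan()].
#' @param n_cumulative Optional cumulative recruitment after each batch;
#'   defaults to `plan$batch_size * seq_along(bf_trajectory)`.
#' @return A list of class `sequential_decision`: `decision` (`support_H1`,
#'   `support_H0`, `inconclusive_max_n` or `continue`), `stop_batch`,
#'   `n_at_stop`, `bf_trajectory`.
#' @export
#' @examples
#' sequential_decision(c(2.1, 5.27), sequential_plan())$decision  # support_H1
sequential_decision <- function(bf_trajectory, plan = sequential_plan(),
                                n_cumulative = NULL) {
  if (!inherits(plan, "sequential_plan")) {
    abort_config("plan must be a sequential_plan")
  }
  if (!length(bf_trajectory)) abort_data("empty Bayes-factor trajectory")
  if (any(!is.finite(bf_trajectory)) || any(bf_trajectory <= 0)) {
    abort_data("Bayes factors must be finite and positive")
  }
  if (is.null(n_cumulative)) {
    n_cumulative <- plan$batch_size * seq_along(bf_trajectory)
  }
  decision <- NULL; stop_batch <- length(bf_trajectory)
  for (i in seq_along(bf_trajectory)) {
    bf <- bf_trajectory[i]
    if (bf > plan$bf_upper) { decision <- "support_H1"; stop_batch <- i; break }
    if (bf < plan$bf_lower) { decision <- "support_H0"; stop_batch <- i; break }
  }
  if (is.null(decision)) {
    decision <- if (n_cumulative[length(n_cumulative)] >= plan$n_max) {
      "inconclusive_max_n"
    } else "continue"
  }
  structure(list(decision = decision, stop_batch = stop_batch,
                 n_at_stop = min(n_cumulative[stop_batch], plan$n_max),
                 bf_trajectory = bf_trajectory, plan = plan),
            class = "sequential_decision")
}

#' @export
print.sequential_decision <- function(x, ...) {
  cat(sprintf(
    "Sequential decision: %s after batch %d (n = %d)\n  BF10 per batch: %s\n",
    x$decision, x$stop_batch, x$n_at_stop,
    paste(signif(x$bf_trajectory, 4), collapse = ", ")))
  invisible(x)
}

#' Operating characteristics of the sequential plan
#'
#' Monte-Carlo evaluation of the batch-wise stopping rule: cohorts are
#' simulated at the participant-summary level (observed per-participant
#' RT-CIT effects drawn from each condition's Normal(probe_effect_mean_ms,
#' probe_effect_sd_ms); at this level the configured SD plays the role of the
#' observed between-participant spread), batches alternate between conditions,
#' and the cumulative between-condition BF10 is tracked until the plan stops.
#'
#' @param config A [cit_config()] giving the true per-condition effect
#'   distributions.
#' @param plan A [sequential_plan()].
#' @param n_sims Number of simulated experiments.
#' @param seed RNG seed.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return A list of class `sequential_oc`: `decisions` (data frame with the
#'   Monte-Carlo probability and its standard error per decision), and
#'   `mean_stop_n`.
#' @export
sequential_operating_characteristics <- function(config,
                                                 plan = sequential_plan(),
                                                 n_sims = 100L, seed = 1L,
                                                 prior_scale = sqrt(2) / 2) {
  validate_cit_config(config)
  if (n_sims < 1) abort_config("n_sims must be >= 1")
  max_batches <- ceiling(plan$n_max / plan$batch_size)
  n1b <- ceiling(plan$batch_size / 2)
  n2b <- plan$batch_size - n1b
  mu <- vapply(cit_conditions(), function(cond)
    cond_param(config$probe_effect_mean_ms, cond, "probe_effect_mean_ms"),
    numeric(1))
  sg <- vapply(cit_conditions(), function(cond)
    cond_param(config$probe_effect_sd_ms, cond, "probe_effect_sd_ms"),
    numeric(1))
  results <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      g1 <- numeric(0); g2 <- numeric(0); traj <- numeric(0)
      for (b in seq_len(max_batches)) {
        g1 <- c(g1, stats::rnorm(n1b, mu[[1]], sg[[1]]))
        g2 <- c(g2, stats::rnorm(n2b, mu[[2]], sg[[2]]))
        ts <- two_sample_contrast(mean(g1), stats::sd(g1), length(g1),
                                  mean(g2), stats::sd(g2), length(g2))
        traj <- c(traj, jzs_bf_two_sample(ts$t, length(g1), length(g2),
                                          prior_scale)$bf10)
        dec <- sequential_decision(traj, plan)
        if (dec$decision != "continue") break
      }
      c(decision = match(dec$decision,
                         c("support_H1", "support_H0", "inconclusive_max_n")),
        n_stop = dec$n_at_stop)
    }, numeric(2))
  })
  labels <- c("support_H1", "support_H0", "inconclusive_max_n")
  p <- vapply(1:3, function(k) mean(results["decision", ] == k), numeric(1))
  decisions <- data.frame(
    decision = labels, prob = p,
    mc_se = sqrt(p * (1 - p) / n_sims), stringsAsFactors = FALSE)
  structure(list(decisions = decisions,
                 mean_stop_n = mean(results["n_stop", ]),
                 n_sims = n_sims, plan = plan, seed = seed),
            class = "sequential_oc")
}

#' @export
print.sequential_oc <- function(x, ...) {
  cat(sprintf("Sequential plan operating characteristics (%d simulations)\n",
              x$n_sims))
  for (i in seq_len(nrow(x$decisions))) {
    cat(sprintf("  P(%s) = %.3f (MC SE %.3f)\n", x$decisions$decision[i],
                x$decisions$prob[i], x$decisions$mc_se[i]))
  }
  cat(sprintf("  mean stopping N = %.1f\n", x$mean_stop_n))
  invisible(x)
}
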