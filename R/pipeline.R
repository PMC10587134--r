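# End-to-end pipeline: simulate -> preprocess -> analyze -> roc -> report.
# Every stochastic stage consumes a seed derived from the master seed, so a
# rerun with the same configuration is bit-identical and stages can be
# re-executed in isolation.

#' Configure the analysis pipeline
#'
#' @param generator A [cit_config()]; its own `seed` is overridden by the
#'   seed derived from `seed` here.
#' @param seed Master seed for the whole pipeline.
#' @param out_dir Directory for serialized artifacts (created if needed);
#'   `NULL` keeps everything in memory.
#' @param trials Optional pre-existing trial table (or path to a trial-log
#'   CSV); when supplied, generation is skipped.
#' @param n_boot Bootstrap replicates for the detection analysis.
#' @param prior_scale Cauchy prior scale for all Bayes factors.
#' @param ci_critical `"z"` or `"t"` critical values for report CIs.
#' @param bootstrap_scheme `"resample"` or `"naive_only"` (see
#'   [bootstrap_auc()]).
#' @param boot_ci `"percentile"` or `"normal"` bootstrap CI.
#' @param naive_sd_literal Use the literal (un-rooted) naive-null expression.
#' @param misses_as_errors Count misses as errors in the 50% QC criterion.
#' @param verbose Log one line per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cit_config(), seed = 1L,
                            out_dir = NULL, trials = NULL, n_boot = 100L,
                            prior_scale = sqrt(2) / 2, ci_critical = "z",
                            bootstrap_scheme = "resample",
                            boot_ci = "percentile",
                            naive_sd_literal = FALSE,
                            misses_as_errors = FALSE, verbose = TRUE) {
  validate_cit_config(generator)
  structure(list(generator = generator, seed = as.integer(seed),
                 out_dir = out_dir, trials = trials, n_boot = n_boot,
                 prior_scale = prior_scale,
                 ci_critical = match.arg(ci_critical, c("z", "t")),
                 bootstrap_scheme = match.arg(bootstrap_scheme,
                                              c("resample", "naive_only")),
                 boot_ci = match.arg(boot_ci, c("percentile", "normal")),
                 naive_sd_literal = isTRUE(naive_sd_literal),
                 misses_as_errors = isTRUE(misses_as_errors),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf(paste0("[rtcit] ", fmt), ...))
}

# One report cell: group statistics of per-participant summaries for a
# condition x stratum, with CIs, within-d and the one-sample BF10 against 0.
summarize_cell <- function(summ, condition, stratum, config) {
  rows <- summ[summ$condition == condition & summ$probe_type == stratum, ,
               drop = FALSE]
  if (nrow(rows) < 2) {
    abort_data(sprintf(
      "report cell %s / %s: fewer than 2 participants", condition, stratum))
  }
  g <- group_summary(rows$rt_cit_effect)
  ci <- mean_effect_ci(g$mean, g$sd, g$n, critical = config$ci_critical)
  d <- cohens_d_within(g$mean, g$sd, g$n, critical = config$ci_critical)
  t1 <- g$mean / (g$sd / sqrt(g$n))
  bf <- jzs_bf_one_sample(t1, g$n, prior_scale = config$prior_scale)
  data.frame(
    condition = condition, probe_type = stratum, n = g$n,
    m_probes = mean(rows$mean_rt_probe), sd_probes = stats::sd(rows$mean_rt_probe),
    m_irrelevants = mean(rows$mean_rt_irrelevant),
    sd_irrelevants = stats::sd(rows$mean_rt_irrelevant),
    effect_mean = g$mean, effect_sd = g$sd,
    effect_ci_low = ci$ci_low, effect_ci_high = ci$ci_high,
    d = d$point, d_ci_low = d$ci_low, d_ci_high = d$ci_high,
    t_vs_zero = t1, bf10_vs_zero = bf$bf10,
    stringsAsFactors = FALSE)
}

#' Assemble the cohort report
#'
#' Builds the summary-table structure of the analysis — per condition the
#' pooled, names-only and cities-only rows (mean probe and irrelevant RTs,
#' RT-CIT effect with CI, within-condition d with CI, one-sample BF10) — plus
#' the between-condition contrast, the detection (AUC) results, and the
#' exclusion tally.
#'
#' @param summaries Participant-summary table from [cit_summaries()].
#' @param qc QC table from [cit_summaries()] (exclusion audit).
#' @param config A [pipeline_config()] (toggles for CIs and priors).
#' @param auc_results Optional detection results, a list with
#'   `by_condition` (named list of [bootstrap_auc()] results) and
#'   `comparison` (a [compare_aucs()] result), as assembled by
#'   [run_pipeline()].
#' @return A list of class `cit_report`: `cells`, `contrast`, `auc` (may be
#'   `NULL` when built without a detection stage), `exclusions`.
#' @export
build_report <- function(summaries, qc, config = pipeline_config(),
                         auc_results = NULL) {
  strata <- c("names+cities", "names", "cities")
  cells <- do.call(rbind, lapply(cit_conditions(), function(cond) {
    do.call(rbind, lapply(strata, function(st)
      summarize_cell(summaries, cond, st, config)))
  }))
  pooled <- lapply(cit_conditions(), function(cond)
    group_summary(summaries$rt_cit_effect[
      summaries$condition == cond & summaries$probe_type == "names+cities"]))
  names(pooled) <- cit_conditions()
  ts <- two_sample_contrast(
    pooled$conflict$mean, pooled$conflict$sd, pooled$conflict$n,
    pooled$no_conflict$mean, pooled$no_conflict$sd, pooled$no_conflict$n,
    critical = config$ci_critical)
  bf <- jzs_bf_two_sample(ts$t, pooled$conflict$n, pooled$no_conflict$n,
                          prior_scale = config$prior_scale)
  contrast <- c(ts, list(bf10 = bf$bf10, bf01 = bf$bf01,
                         n1 = pooled$conflict$n, n2 = pooled$no_conflict$n))
  tally <- table(factor(qc$exclusion_reason[qc$excluded],
                        levels = c("high_error", "incomplete", "duplicate")))
  structure(list(cells = cells, contrast = contrast, auc = auc_results,
                 exclusions = as.data.frame(tally,
                                            responseName = "n_excluded",
                                            stringsAsFactors = FALSE)),
            class = "cit_report")
}

#' @export
format.cit_report <- function(x, ...) {
  lines <- c("RT-CIT cohort report", "====================", "")
  for (cond in unique(x$cells$condition)) {
    lines <- c(lines, sprintf("Condition: %s", cond))
    sub <- x$cells[x$cells$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lines <- c(lines, sprintf(
        "  %-12s n=%3d  probes %s (%s)  irrelevants %s (%s)  effect %s [%s; %s]  d %s [%s; %s]  BF10 %s",
        r$probe_type, r$n, fmt2(r$m_probes), fmt2(r$sd_probes),
        fmt2(r$m_irrelevants), fmt2(r$sd_irrelevants),
        fmt2(r$effect_mean), fmt2(r$effect_ci_low), fmt2(r$effect_ci_high),
        fmt2(r$d), fmt2(r$d_ci_low), fmt2(r$d_ci_high),
        format(signif(r$bf10_vs_zero, 4))))
    }
  }
  cn <- x$contrast
  lines <- c(lines, "", sprintf(
    "Between conditions: difference %s [%s; %s], t(%s) = %s, p = %.3g, d = %s, BF10 = %s",
    fmt2(cn$difference), fmt2(cn$ci_low), fmt2(cn$ci_high),
    format(round(cn$df, 1)), fmt2(cn$t), cn$p, fmt2(cn$d),
    format(signif(cn$bf10, 4))))
  if (!is.null(x$auc)) {
    for (cond in names(x$auc$by_condition)) {
      a <- x$auc$by_condition[[cond]]
      lines <- c(lines, sprintf(
        "AUC (%s): %s [%s; %s] over %d bootstrap replicates",
        cond, fmt2(a$mean_auc), fmt2(a$ci_low), fmt2(a$ci_high), a$n_boot))
    }
    lines <- c(lines, sprintf("AUC comparison: Z = %s, p = %.3g",
                              fmt2(x$auc$comparison$z), x$auc$comparison$p))
  }
  excl <- x$exclusions
  lines <- c(lines, "", sprintf(
    "Exclusions: %s",
    paste(sprintf("%s = %d", excl$Var1, excl$n_excluded), collapse = ", ")))
  paste(lines, collapse = "\n")
}

#' @export
print.cit_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes generation (or ingestion), QC and filtering, effect scoring, the
#' frequentist and Bayesian contrasts, the bootstrapped detection analysis per
#' condition, and report assembly. Stage seeds are derived deterministically
#' from `config$seed`; a rerun with an identical configuration produces
#' identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cit_pipeline_result`: `report` (a `cit_report`),
#'   `summaries`, `qc`, `truth` (when generated), `trials`, and — when
#'   `out_dir` is set — `paths` of the serialized artifacts.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(
#'   generator = cit_config(n_per_condition = 20), seed = 42, n_boot = 50,
#'   verbose = FALSE))
#' res$report
#' }
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("config must be a pipeline_config")
  }
  seeds <- derive_seeds(config$seed, 4L)
  truth <- NULL
  if (is.null(config$trials)) {
    gen <- config$generator
    gen$seed <- seeds[1]
    cohort <- generate_cohort(gen)
    trials <- cohort$trials
    truth <- cohort$truth
    pipe_log(config, "simulate: %d participants, %d trials",
             nrow(truth), nrow(trials))
  } else {
    trials <- if (is.character(config$trials)) read_trials(config$trials)
      else validate_trials(config$trials)
    pipe_log(config, "ingest: %d trials", nrow(trials))
  }

  s <- cit_summaries(trials, misses_as_errors = config$misses_as_errors)
  n_excluded <- sum(s$qc$excluded)
  pipe_log(config, "preprocess: %d participants retained, %d excluded (%s)",
           sum(!s$qc$excluded), n_excluded,
           paste(names(table(s$qc$exclusion_reason[s$qc$excluded])),
                 table(s$qc$exclusion_reason[s$qc$excluded]),
                 sep = "=", collapse = ", "))

  # Detection analysis per condition, seeded independently.
  auc_by_cond <- list()
  for (i in seq_along(cit_conditions())) {
    cond <- cit_conditions()[i]
    dcits <- s$summaries$dcit[s$summaries$condition == cond &
                                s$summaries$probe_type == "names+cities"]
    spec <- naive_null_spec(length(dcits),
                            literal = config$naive_sd_literal)
    auc_by_cond[[cond]] <- bootstrap_auc(
      dcits, spec, n_boot = config$n_boot, seed = seeds[1 + i],
      scheme = config$bootstrap_scheme, ci = config$boot_ci)
  }
  cmp <- compare_aucs(
    auc_by_cond$conflict$mean_auc,
    auc_by_cond$conflict$spec$n, auc_by_cond$conflict$spec$n,
    auc_by_cond$no_conflict$mean_auc,
    auc_by_cond$no_conflict$spec$n, auc_by_cond$no_conflict$spec$n)
  pipe_log(config, "roc: AUC conflict %.3f, no_conflict %.3f, Z = %.2f",
           auc_by_cond$conflict$mean_auc, auc_by_cond$no_conflict$mean_auc,
           cmp$z)

  report <- build_report(s$summaries, s$qc, config,
                         auc_results = list(by_condition = auc_by_cond,
                                            comparison = cmp))
  result <- structure(
    list(report = report, summaries = s$summaries, qc = s$qc, truth = truth,
         trials = trials, config = config, stage_seeds = seeds),
    class = "cit_pipeline_result")
  if (!is.null(config$out_dir)) {
    result$paths <- write_pipeline_artifacts(result, config$out_dir)
    pipe_log(config, "report: artifacts in %s", config$out_dir)
  }
  result
}

#' @export
print.cit_pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

# Serialize every intermediate the report is computed from, so each rendered
# number can be recomputed from the artifacts alone.
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    summaries = file.path(out_dir, "participant_summaries.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    replicates = file.path(out_dir, "auc_replicates.csv"),
    roc = file.path(out_dir, "roc_points.csv"),
    results = file.path(out_dir, "results.json"),
    report = file.path(out_dir, "report.txt"))
  write_trials(result$trials, paths$trials)
  if (!is.null(result$truth)) {
    paths$truth <- file.path(out_dir, "truth.csv")
    utils::write.csv(result$truth, paths$truth, row.names = FALSE)
  }
  utils::write.csv(result$summaries, paths$summaries, row.names = FALSE)
  utils::write.csv(result$qc, paths$exclusions, row.names = FALSE)
  aucs <- result$report$auc$by_condition
  reps <- do.call(rbind, lapply(names(aucs), function(cond)
    data.frame(condition = cond,
               replicate = seq_len(aucs[[cond]]$n_boot),
               auc = aucs[[cond]]$replicates, stringsAsFactors = FALSE)))
  utils::write.csv(reps, paths$replicates, row.names = FALSE)
  roc <- do.call(rbind, lapply(names(aucs), function(cond) {
    dcits <- result$summaries$dcit[result$summaries$condition == cond &
                                     result$summaries$probe_type == "names+cities"]
    naive <- simulate_naive(aucs[[cond]]$spec, aucs[[cond]]$spec$n,
                            seed = result$stage_seeds[4])
    cbind(condition = cond, roc_points(dcits, naive))
  }))
  utils::write.csv(roc, paths$roc, row.names = FALSE)
  cells <- result$report$cells
  jsonlite::write_json(
    list(cells = cells, contrast = result$report$contrast,
         auc = lapply(aucs, function(a)
           list(mean_auc = a$mean_auc, ci_low = a$ci_low,
                ci_high = a$ci_high, n_boot = a$n_boot,
                naive_n = a$spec$n, naive_sd = a$spec$sd)),
         auc_comparison = result$report$auc$comparison,
         exclusions = result$report$exclusions,
         seed = result$config$seed),
    paths$results, auto_unbox = TRUE, digits = NA)
  writeLines(format(result$report), paths$report)
  paths
}

#' Batch-wise evidential flow
#'
#' Reconstructs the sequential analysis: after each cumulative batch of trial
#' logs the cohort is re-preprocessed, the between-condition contrast is
#' recomputed, and the BF10 trajectory is fed to [sequential_decision()].
#'
#' @param batches A list of trial tables, one per recruitment batch, in
#'   chronological order (each element contains only that batch's trials).
#' @param plan A [sequential_plan()].
#' @param prior_scale Cauchy prior scale.
#' @param misses_as_errors Passed to [cit_summaries()].
#' @return A list of class `evidential_flow`: `flow` (data frame with batch,
#'   cumulative recruited and analysed n, t, and BF10) and `decision`.
#' @export
evidential_flow <- function(batches, plan = sequential_plan(),
                            prior_scale = sqrt(2) / 2,
                            misses_as_errors = FALSE) {
  if (!length(batches)) abort_data("need at least one complete batch")
  flow <- vector("list", length(batches))
  cum <- NULL
  for (b in seq_along(batches)) {
    cum <- rbind(cum, batches[[b]])
    s <- cit_summaries(cum, by_probe_type = FALSE,
                       misses_as_errors = misses_as_errors)
    eff <- split(s$summaries$rt_cit_effect, s$summaries$condition)
    if (length(eff) < 2 || any(lengths(eff) < 2)) {
      abort_data(sprintf(
        "batch %d: both conditions need >= 2 retained participants", b))
    }
    g1 <- group_summary(eff$conflict); g2 <- group_summary(eff$no_conflict)
    ts <- two_sample_contrast(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n)
    bf <- jzs_bf_two_sample(ts$t, g1$n, g2$n, prior_scale = prior_scale)
    flow[[b]] <- data.frame(
      batch = b, n_recruited = length(unique(cum$participant_id)),
      n_analyzed = g1$n + g2$n, t = ts$t, bf10 = bf$bf10)
  }
  flow <- do.call(rbind, flow)
  decision <- sequential_decision(flow$bf10, plan,
                                  n_cumulative = flow$n_recruited)
  structure(list(flow = flow, decision = decision),
            class = "evidential_flow")
}

#' @export
print.evidential_flow <- function(x, ...) {
  cat("Evidential flow (cumulative batches)\n")
  print(x$flow, row.names = FALSE)
  print(x$decision)
  invisible(x)
}
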