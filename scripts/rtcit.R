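#!/usr/bin/env Rscript
# Thin command-line front end over the rtcit package.
#
#   Rscript scripts/rtcit.R <subcommand> [options]
#
# Subcommands:
#   simulate    generate a synthetic cohort and write the trial log
#   preprocess  QC + filters + participant summaries from a trial log
#   analyze     effect sizes, contrast and Bayes factors from a trial log
#   roc         detection analysis (bootstrapped AUCs) from a trial log
#   report      full report from a trial log
#   all         simulate + full analysis, writing every artifact

suppressPackageStartupMessages({
  library(optparse)
  library(rtcit)
})

opts <- list(
  make_option("--trials", type = "character", default = NULL,
              help = "input trial-log CSV (subcommands other than simulate)"),
  make_option("--out-dir", type = "character", default = "rtcit_out",
              dest = "out_dir", help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [default %default]"),
  make_option("--n-conflict", type = "integer", default = 131L,
              dest = "n_conflict", help = "participants, conflict condition"),
  make_option("--n-no-conflict", type = "integer", default = 161L,
              dest = "n_no_conflict", help = "participants, no-conflict condition"),
  make_option("--n-contaminated", type = "integer", default = 0L,
              dest = "n_contaminated", help = "engineered high-error participants"),
  make_option("--n-boot", type = "integer", default = 100L, dest = "n_boot",
              help = "bootstrap replicates for the AUC [default %default]"),
  make_option("--prior-scale", type = "double", default = sqrt(2) / 2,
              dest = "prior_scale", help = "Cauchy prior scale [default 0.707]"),
  make_option("--ci", type = "character", default = "z",
              help = "CI critical values: z or t [default %default]"),
  make_option("--bootstrap-scheme", type = "character", default = "resample",
              dest = "bootstrap_scheme", help = "resample or naive_only"),
  make_option("--naive-sd-literal", action = "store_true", default = FALSE,
              dest = "naive_sd_literal",
              help = "use the un-rooted naive-null expression"),
  make_option("--quiet", action = "store_true", default = FALSE,
              help = "suppress stage logging")
)

parser <- OptionParser(
  usage = "usage: Rscript scripts/rtcit.R <simulate|preprocess|analyze|roc|report|all> [options]",
  option_list = opts)
parsed <- parse_args2(parser)
if (length(parsed$args) != 1L) {
  print_help(parser); quit(status = 2L)
}
cmd <- parsed$args
o <- parsed$options

config <- pipeline_config(
  generator = cit_config(
    n_per_condition = c(conflict = o$n_conflict,
                        no_conflict = o$n_no_conflict),
    n_contaminated = o$n_contaminated),
  seed = o$seed, out_dir = o$out_dir, trials = o$trials,
  n_boot = o$n_boot, prior_scale = o$prior_scale, ci_critical = o$ci,
  bootstrap_scheme = o$bootstrap_scheme,
  naive_sd_literal = o$naive_sd_literal, verbose = !o$quiet)

dir.create(o$out_dir, recursive = TRUE, showWarnings = FALSE)

if (cmd == "simulate") {
  gen <- config$generator
  gen$seed <- o$seed
  cohort <- generate_cohort(gen)
  write_trials(cohort$trials, file.path(o$out_dir, "trials.csv"))
  write.csv(cohort$truth, file.path(o$out_dir, "truth.csv"),
            row.names = FALSE)
  cat("wrote", file.path(o$out_dir, "trials.csv"), "\n")
} else if (cmd == "preprocess") {
  if (is.null(o$trials)) stop("preprocess needs --trials")
  s <- cit_summaries(read_trials(o$trials))
  write.csv(s$summaries, file.path(o$out_dir, "participant_summaries.csv"),
            row.names = FALSE)
  write.csv(s$qc, file.path(o$out_dir, "exclusions.csv"), row.names = FALSE)
  cat("retained", sum(!s$qc$excluded), "of", nrow(s$qc), "participants\n")
} else if (cmd %in% c("analyze", "roc", "report", "all")) {
  res <- run_pipeline(config)
  if (cmd == "analyze") {
    print(res$report$cells)
    cn <- res$report$contrast
    cat(sprintf("difference %.2f ms, t(%d) = %.2f, p = %.3g, BF10 = %.4g\n",
                cn$difference, cn$df, cn$t, cn$p, cn$bf10))
  } else if (cmd == "roc") {
    for (cond in names(res$report$auc$by_condition)) {
      print(res$report$auc$by_condition[[cond]])
    }
  } else {
    print(res$report)
  }
} else {
  print_help(parser); quit(status = 2L)
}
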