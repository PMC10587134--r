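# The synthetic cohort generator: protocol structure, RT model, determinism,
# and the trial-log round trip.

test_that("every session respects the MPP protocol structure", {
  cohort <- generate_cohort(small_config())
  trials <- cohort$trials
  for (pid in unique(trials$participant_id)) {
    tp <- trials[trials$participant_id == pid, ]
    expect_identical(nrow(tp), 288L)
    expect_identical(as.integer(table(tp$block)), rep(72L, 4L))
    for (b in 1:4) {
      tb <- tp[tp$block == b, ]
      counts <- table(factor(tb$stimulus_type, cit_stimulus_types()))
      expect_identical(as.integer(counts), c(12L, 48L, 12L))
      expect_identical(as.integer(table(tb$item_id)), rep(6L, 12L))
      expect_identical(tb$trial_index, 1:72)
    }
    # no immediate item repeats, including across block boundaries
    expect_false(any(tp$item_id[-1] == tp$item_id[-nrow(tp)]))
  }
  expect_true(all(is.na(trials$rt_ms) |
                    (trials$rt_ms > 0 & trials$rt_ms <= 1500)))
  expect_identical(is.na(trials$rt_ms), !trials$responded)
})

test_that("identical config and seed give byte-identical cohorts", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a, b)
  d <- generate_cohort(cit_config(n_per_condition = 3, seed = 12L))
  expect_false(identical(a$trials$rt_ms, d$trials$rt_ms))
})

test_that("noise-free limit yields the configured probe effect exactly", {
  cfg <- cit_config(n_per_condition = 2, probe_effect_mean_ms = 35,
                    probe_effect_sd_ms = 0, trial_sd_ms = 0,
                    error_rate_by_type = c(probe = 0, irrelevant = 0,
                                           target = 0),
                    miss_rate = 0, seed = 3L)
  cohort <- generate_cohort(cfg)
  kept <- filter_trials(cohort$trials)
  effects <- vapply(split(kept, kept$participant_id), function(tp) {
    m <- tapply(tp$rt_ms, tp$stimulus_type, mean)
    m[["probe"]] - m[["irrelevant"]]
  }, numeric(1))
  expect_equal(unname(effects), rep(35, 4))
})

test_that("naive participants have no probe effect on average", {
  cfg <- cit_config(n_per_condition = 40, knowledgeable = FALSE, seed = 21L)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$truth$true_effect_ms == 0))
  s <- cit_summaries(cohort$trials, by_probe_type = FALSE)
  eff <- s$summaries$rt_cit_effect
  mc_se <- sd(eff) / sqrt(length(eff))
  expect_lt(abs(mean(eff)), 3 * mc_se)
})

test_that("cohort effects are calibrated to the configured population", {
  cfg <- cit_config(n_per_condition = c(conflict = 200, no_conflict = 2),
                    seed = 31L)
  cohort <- generate_cohort(cfg)
  s <- cit_summaries(cohort$trials, by_probe_type = FALSE)
  eff <- s$summaries$rt_cit_effect[s$summaries$condition == "conflict"]
  n <- length(eff)
  expect_lt(abs(mean(eff) - 35.84), 3 * sd(eff) / sqrt(n))
  # the truth table carries the population of true effects
  true_eff <- cohort$truth$true_effect_ms[cohort$truth$condition == "conflict"]
  expect_lt(abs(mean(true_eff) - 35.84), 3 * sd(true_eff) / sqrt(n))
  expect_lt(abs(sd(true_eff) - 34.14), 3 * 34.14 / sqrt(2 * n))
  # observed spread exceeds the true spread by trial-sampling noise
  expect_gt(sd(eff), sd(true_eff))
})

test_that("engineered contamination is caught by participant QC", {
  cfg <- cit_config(n_per_condition = 5, n_contaminated = 2, seed = 41L)
  cohort <- generate_cohort(cfg)
  qc <- participant_qc(cohort$trials)
  expect_identical(sum(qc$exclusion_reason == "high_error"), 2L)
  expect_identical(qc$participant_id[qc$exclusion_reason == "high_error"],
                   cohort$truth$participant_id[cohort$truth$contaminated])
})

test_that("invalid generator configurations are rejected", {
  expect_error(cit_config(n_per_condition = 0), class = "rtcit_config_error")
  expect_error(cit_config(miss_rate = 1.2), class = "rtcit_config_error")
  expect_error(cit_config(baseline_sd_ms = -1), class = "rtcit_config_error")
  expect_error(cit_config(error_rate_by_type = c(probe = 0.1)),
               class = "rtcit_config_error")
  expect_error(cit_config(n_per_condition = 2, n_contaminated = 5),
               class = "rtcit_config_error")
  expect_error(generate_session(small_config(), "p", "sideways"),
               class = "rtcit_config_error")
})

test_that("practice-phase criteria follow the printed thresholds", {
  expect_true(practice_pass(0.5, 500, 1))
  expect_false(practice_pass(0.51, 500, 1))
  expect_false(practice_pass(0.1, 150, 2))   # mean RT must exceed 150
  expect_true(practice_pass(0.1, 151, 2))
  expect_false(practice_pass(0.1, 800, 3))   # and stay under 800
  expect_true(practice_pass(0.1, 799, 3))
  expect_error(practice_pass(0.1, 500, 4), class = "rtcit_config_error")
})

test_that("trial logs round-trip through CSV exactly", {
  cohort <- generate_cohort(small_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(cohort$trials, path)
  back <- read_trials(path)
  expect_identical(back, cohort$trials)
})

test_that("malformed trial logs fail with row- and column-level messages", {
  trials <- generate_cohort(cit_config(n_per_condition = 1, seed = 2))$trials
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- trials
  bad$stimulus_type[5] <- "probee"
  expect_error(write_trials(bad, path), "row 5.*stimulus_type.*probee",
               class = "rtcit_parse_error")
  bad <- trials
  bad$rt_ms[8] <- 1600  # outside the 1500 ms response window
  utils::write.csv(bad[rtcit:::trial_columns()], path, row.names = FALSE,
                   na = "")
  expect_error(read_trials(path), "row 8.*rt_ms.*1500",
               class = "rtcit_parse_error")

  bad <- trials[, setdiff(names(trials), "correct")]
  expect_error(validate_trials(bad), "missing column.*correct",
               class = "rtcit_parse_error")
  bad <- trials
  bad$rt_ms[3] <- NA  # RT absent although a response was made
  expect_error(validate_trials(bad), "row 3",
               class = "rtcit_parse_error")
})
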