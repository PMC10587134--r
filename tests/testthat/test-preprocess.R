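# Trial filters, participant QC, scoring, and rating scores.

test_that("trial filters drop wrong presses, <150 ms, >800 ms, and misses", {
  trials <- make_trials(
    stimulus_type = "irrelevant",
    rt_ms = c(400, 400, 140, 810, 150, 800, NA),
    responded = c(rep(TRUE, 6), FALSE),
    correct = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  kept <- filter_trials(trials)
  expect_equal(kept$rt_ms, c(400, 150, 800))  # boundaries retained
  # idempotent and non-destructive
  expect_identical(filter_trials(kept), kept)
  expect_identical(nrow(trials), 7L)
  # everything wrong -> empty
  allwrong <- make_trials(rt_ms = rep(400, 5), correct = FALSE)
  expect_identical(nrow(filter_trials(allwrong)), 0L)
  # no rule fires -> identity
  clean <- make_trials(rt_ms = c(150, 400, 800))
  expect_identical(filter_trials(clean), clean)
})

test_that("the 50% wrong-button criterion excludes at the boundary", {
  at <- make_session_trials("p_at", wrong = c(probe = 48L, irrelevant = 0L,
                                              target = 0L))
  below <- make_session_trials("p_below", wrong = c(probe = 47L,
                                                    irrelevant = 0L,
                                                    target = 0L))
  qc <- participant_qc(rbind(at, below), expected_n = 288L)
  expect_identical(qc$exclusion_reason, c("high_error", "none"))
  expect_equal(qc$error_rate_probe, c(0.5, 47 / 96))
})

test_that("duplicate and incomplete sessions are excluded wholesale", {
  one <- make_session_trials("dup")
  dup <- rbind(one, one)                       # two full sessions, one id
  part <- make_session_trials("part")[1:200, ] # incomplete
  ok <- make_session_trials("ok")
  qc <- participant_qc(rbind(dup, part, ok), expected_n = 288L)
  expect_identical(qc$exclusion_reason[match(c("dup", "part", "ok"),
                                             qc$participant_id)],
                   c("duplicate", "incomplete", "none"))
})

test_that("misses can optionally count as errors in QC", {
  tr <- make_session_trials("m")
  probe_idx <- which(tr$stimulus_type == "probe")[1:50]
  tr$responded[probe_idx] <- FALSE
  tr$correct[probe_idx] <- FALSE
  tr$rt_ms[probe_idx] <- NA
  expect_identical(participant_qc(tr)$exclusion_reason, "none")
  expect_identical(participant_qc(tr, misses_as_errors = TRUE)$exclusion_reason,
                   "high_error")
})

test_that("a stimulus type with no presented trials is a data error", {
  tr <- make_session_trials("z")
  expect_error(participant_qc(tr[tr$stimulus_type != "target", ]),
               "z.*target", class = "rtcit_data_error")
})

test_that("participant summaries match hand computation", {
  tr <- make_trials(stimulus_type = rep(c("probe", "irrelevant"), c(2, 4)),
                    rt_ms = c(500, 520, 460, 480, 470, 490))
  s <- summarize_participant(tr)
  expect_equal(s$rt_cit_effect, 35)
  expect_equal(s$sd_irrelevant, sqrt(500 / 3), tolerance = 1e-12)
  expect_equal(round(s$sd_irrelevant, 3), 12.910)
  expect_equal(round(s$dcit, 3), 2.711)
  expect_identical(c(s$n_valid_probe, s$n_valid_irrelevant), c(2L, 4L))

  # zero effect when probes sit at the irrelevant mean
  tr0 <- make_trials(stimulus_type = rep(c("probe", "irrelevant"), c(1, 4)),
                     rt_ms = c(475, 460, 480, 470, 490))
  expect_equal(summarize_participant(tr0)$dcit, 0)

  # degenerate irrelevant variance
  trc <- make_trials(stimulus_type = rep(c("probe", "irrelevant"), c(1, 4)),
                     rt_ms = c(500, 470, 470, 470, 470))
  expect_error(summarize_participant(trc), "p1.*irrelevant",
               class = "rtcit_data_error")
  expect_error(
    summarize_participant(make_trials(stimulus_type = rep("irrelevant", 4))),
    "probe", class = "rtcit_data_error")
})

test_that("dCIT is invariant to shifting and positive rescaling of RTs", {
  cohort <- generate_cohort(small_config())
  filtered <- filter_trials(cohort$trials)
  for (pid in unique(filtered$participant_id)[1:3]) {
    fp <- filtered[filtered$participant_id == pid, ]
    base <- summarize_participant(fp)$dcit
    sh <- fp; sh$rt_ms <- sh$rt_ms + 57
    expect_equal(summarize_participant(sh)$dcit, base, tolerance = 1e-12)
    sc <- fp; sc$rt_ms <- sc$rt_ms * 1.8
    expect_equal(summarize_participant(sc)$dcit, base, tolerance = 1e-12)
  }
})

test_that("cohort preprocessing ties QC, filters and strata together", {
  cfg <- cit_config(n_per_condition = 4, n_contaminated = 1, seed = 9L)
  cohort <- generate_cohort(cfg)
  s <- cit_summaries(cohort$trials)
  expect_identical(sum(s$qc$excluded), 1L)
  kept <- sum(!s$qc$excluded)
  expect_identical(nrow(s$summaries), kept * 3L)  # pooled + names + cities
  expect_setequal(unique(s$summaries$probe_type),
                  c("names+cities", "names", "cities"))
  # QC error rates are pre-filter: the contaminated participant's probe
  # errors are all wrong presses, which the trial filters would have removed
  expect_gte(s$qc$error_rate_probe[s$qc$excluded], 0.5)
})

test_that("significance difference scores follow the probe-irrelevant rule", {
  r <- data.frame(participant_id = rep(c("a", "b", "c"), each = 4),
                  role = rep(c("probe", "probe", "irrelevant", "irrelevant"),
                             3),
                  rating = c(4, 6, 5, 5,    # a: mean 5 - 5 = 0
                             9, 9, 1, 1,    # b: +8
                             2, 4, 5, 7))   # c: 3 - 6 = -3
  s <- significance_difference_score(r)
  expect_equal(s$score[match(c("a", "b", "c"), s$participant_id)],
               c(0, 8, -3))
  expect_error(significance_difference_score(
    data.frame(participant_id = "a", role = "probe", rating = 5)),
    "probe and one irrelevant", class = "rtcit_data_error")
  expect_error(significance_difference_score(
    transform(r, rating = rating + 0.5)), class = "rtcit_data_error")
})

test_that("recruitment bookkeeping sums retained participants", {
  rec <- data.frame(n_recruited = c(50, 40), incomplete = c(5, 2),
                    high_error = c(1, 0))
  out <- analyzed_n(rec)
  expect_equal(out$per_batch, c(44, 38))
  expect_equal(out$n_analyzed, 82)
  expect_error(analyzed_n(data.frame(x = 1)), class = "rtcit_data_error")
})
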