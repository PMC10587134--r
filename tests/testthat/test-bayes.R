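# JZS Bayes factors and the sequential sampling plan.

# Reference values computed once with an independent default-Bayes-factor
# implementation (pingouin 0.6.1, bayesfactor_ttest, Rouder et al.'s
# g-prior integral), Cauchy prior scale sqrt(2)/2.
jzs_reference_two_sample <- data.frame(
  t  = c(0.5, 1.5, 3.2039896398547016, 2.0, 4.0, 0.0, 0.7300643464073145),
  n1 = c(20, 20, 131, 50, 100, 30, 161),
  n2 = c(25, 25, 161, 50, 120, 30, 131),
  bf10 = c(0.3278121032, 0.7275370735, 16.25041931, 1.225133324,
           226.6998322, 0.2623507949, 0.1667956224))
jzs_reference_one_sample <- data.frame(
  t = c(0.5, 1.5, 2.5, 3.5, 5.0, 8.0),
  n = c(20, 20, 40, 60, 100, 131),
  bf10 = c(0.2599826352, 0.6091073076, 2.634594922, 29.68709339,
           5845.298357, 1.226400555e10))

test_that("JZS Bayes factors match an independent implementation to 4 sig digits", {
  for (i in seq_len(nrow(jzs_reference_two_sample))) {
    r <- jzs_reference_two_sample[i, ]
    got <- jzs_bf_two_sample(r$t, r$n1, r$n2)$bf10
    expect_equal(signif(got, 4), signif(r$bf10, 4))
  }
  for (i in seq_len(nrow(jzs_reference_one_sample))) {
    r <- jzs_reference_one_sample[i, ]
    got <- jzs_bf_one_sample(r$t, r$n)$bf10
    expect_equal(signif(got, 4), signif(r$bf10, 4))
  }
})

test_that("BF10 behaves as evidence: reciprocal identity, null at t = 0, monotone in |t|", {
  grid <- seq(0, 6, by = 0.5)
  bfs <- vapply(grid, function(t) {
    b <- jzs_bf_two_sample(t, 40, 45)
    expect_equal(b$bf10 * b$bf01, 1, tolerance = 1e-10)
    b$bf10
  }, numeric(1))
  expect_lt(bfs[1], 1)                    # point null wins at t = 0
  expect_true(all(diff(bfs) > 0))         # strictly increasing in |t|
  expect_equal(jzs_bf_two_sample(-3, 40, 45)$bf10,
               jzs_bf_two_sample(3, 40, 45)$bf10, tolerance = 1e-8)
  one <- vapply(grid, function(t) jzs_bf_one_sample(t, 50)$bf10, numeric(1))
  expect_true(all(diff(one) > 0))
  expect_lt(jzs_bf_one_sample(0, 25)$bf10, 1)
  # a very large standardised effect gives overwhelming evidence
  expect_gt(jzs_bf_one_sample(1.05 * sqrt(131), 131)$bf10, 215)
})

test_that("invalid Bayes-factor inputs are rejected", {
  expect_error(jzs_bf_two_sample(1, 1, 30), class = "rtcit_config_error")
  expect_error(jzs_bf_one_sample(1, 1), class = "rtcit_config_error")
  expect_error(jzs_bf_one_sample(1, 20, prior_scale = 0),
               class = "rtcit_config_error")
  expect_error(jzs_bf_one_sample(Inf, 20), class = "rtcit_data_error")
})

test_that("the sequential rule stops at the first threshold crossing", {
  plan <- sequential_plan()
  d1 <- sequential_decision(c(2.1, 5.27), plan)
  expect_identical(d1$decision, "support_H1")
  expect_identical(d1$stop_batch, 2L)
  expect_identical(d1$n_at_stop, 200L)

  d0 <- sequential_decision(0.15, plan)
  expect_identical(d0$decision, "support_H0")
  expect_identical(d0$stop_batch, 1L)

  dincon <- sequential_decision(c(1, 1, 1), plan)
  expect_identical(dincon$decision, "inconclusive_max_n")
  expect_identical(dincon$n_at_stop, 300L)

  # an unresolved trajectory short of n_max is not inconclusive yet
  expect_identical(sequential_decision(c(1, 1), plan)$decision, "continue")

  # evidence after a crossing is ignored: the rule already stopped
  late <- sequential_decision(c(6, 0.1), plan)
  expect_identical(late$stop_batch, 1L)
  expect_identical(late$decision, "support_H1")

  expect_error(sequential_decision(numeric(0), plan),
               class = "rtcit_data_error")
  expect_error(sequential_plan(bf_upper = 0.5),
               class = "rtcit_config_error")
})

test_that("the rule never reports support from inside the evidential band", {
  plan <- sequential_plan(bf_upper = 5, bf_lower = 0.2, batch_size = 50,
                          n_max = 500)
  set.seed(404)
  for (i in 1:50) {
    traj <- exp(rnorm(10, 0, 1.5))
    dec <- sequential_decision(traj, plan)
    if (dec$decision %in% c("support_H1", "support_H0")) {
      bf_stop <- traj[dec$stop_batch]
      expect_true(bf_stop > plan$bf_upper || bf_stop < plan$bf_lower)
      # and no earlier batch crossed
      earlier <- traj[seq_len(dec$stop_batch - 1)]
      expect_true(all(earlier >= plan$bf_lower & earlier <= plan$bf_upper))
    }
  }
})

test_that("operating characteristics are seeded and match limiting behaviour", {
  plan <- sequential_plan(batch_size = 40, n_max = 120)
  null_cfg <- cit_config(probe_effect_mean_ms = 0, probe_effect_sd_ms = 30)
  oc1 <- sequential_operating_characteristics(null_cfg, plan, n_sims = 30,
                                              seed = 8)
  oc2 <- sequential_operating_characteristics(null_cfg, plan, n_sims = 30,
                                              seed = 8)
  expect_identical(oc1$decisions, oc2$decisions)
  p_h1 <- oc1$decisions$prob[oc1$decisions$decision == "support_H1"]
  expect_lte(p_h1, 0.2)   # false-positive stopping is rare under the null

  big <- cit_config(probe_effect_mean_ms = c(conflict = 90, no_conflict = 0),
                    probe_effect_sd_ms = 30)
  oc3 <- sequential_operating_characteristics(big, plan, n_sims = 10,
                                              seed = 9)
  expect_equal(oc3$decisions$prob[oc3$decisions$decision == "support_H1"], 1)
  expect_equal(oc3$mean_stop_n, 40)  # d = 3 stops at the first batch
})
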