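test_that("exact binomial test matches closed forms and the enumeration oracle", {
  expect_equal(binomial_vs_chance(10, 10), 2 * 0.5^10) # 0.001953125
  expect_equal(binomial_vs_chance(5, 10), 1.0)
  expect_equal(binomial_vs_chance(0, 10), 2 * 0.5^10)
  expect_equal(binomial_vs_chance(35, 40), enum_binom_p(35, 40))
  expect_error(binomial_vs_chance(11, 10), class = "swinecs_config_error")
  expect_error(binomial_vs_chance(-1, 10), class = "swinecs_config_error")
})

test_that("per-contrast performance pools sessions and conserves counts", {
  obs <- observer_preset("good_cs")
  logs <- run_sessions(session_config(seed = 14), obs, 4)
  pooled <- per_contrast_performance(logs)
  expect_equal(pooled$n, rep(40L, 10))
  expect_true(all(pooled$percent_correct >= 0 & pooled$percent_correct <= 100))
  expect_true(all(pooled$p_value_vs_chance > 0 &
                    pooled$p_value_vs_chance <= 1))
  # pooled counts equal the sum of per-session counts
  per_session <- lapply(logs, per_contrast_performance)
  k_sum <- Reduce(`+`, lapply(per_session, `[[`, "k"))
  expect_equal(pooled$k, k_sum)

  # sampled accuracy sits in the 95% binomial band of the generating curve
  for (ct in c(0.1, 1.0)) {
    row <- pooled[pooled$contrast == ct, ]
    p_true <- p_correct(obs, ct)
    band <- qbinom(c(0.025, 0.975), row$n, p_true)
    expect_gte(row$k, band[1])
    expect_lte(row$k, band[2])
  }

  # perfect observer: 100% at every contrast
  pperf <- per_contrast_performance(
    run_session(session_config(seed = 15), observer_preset("perfect")))
  expect_true(all(pperf$percent_correct == 100))
})

test_that("side bias is the side-1 touch percentage with the <25% flag", {
  tr <- make_trials(contrast = rep(1, 60),
                    target_side = rep(c(1, 2), 30),
                    chosen_side = c(rep(1, 30), rep(2, 30)))
  b <- side_bias(tr)
  expect_equal(b$side1_touch_percent, 50)
  expect_false(b$biased)

  tr2 <- make_trials(contrast = rep(1, 60),
                     target_side = rep(c(1, 2), 30),
                     chosen_side = c(rep(1, 10), rep(2, 50)))
  b2 <- side_bias(tr2)
  expect_equal(b2$side1_touch_percent, 100 * 10 / 60, tolerance = 1e-12)
  expect_true(b2$biased)

  # full side-presser: all touches on one side, flagged
  pressy <- observer_params(bias_side = 2, bias_strength = 1)
  b3 <- side_bias(run_session(session_config(seed = 16), pressy))
  expect_equal(b3$side1_touch_percent, 0)
  expect_true(b3$biased)

  aborted_only <- make_trials(contrast = 1, target_side = 1,
                              chosen_side = 1, aborted = TRUE)
  expect_error(side_bias(aborted_only), class = "swinecs_data_error")
})

test_that("bias-accuracy correlation handles monotone and degenerate input", {
  summ <- data.frame(percent_correct = c(90, 80, 70, 60),
                     bias_magnitude = c(0, 10, 20, 40))
  res <- bias_correctness_correlation(summ)
  expect_equal(res$rho, -1)
  expect_equal(res$n_sessions, 4)

  flat <- data.frame(percent_correct = rep(80, 4),
                     bias_magnitude = c(0, 10, 20, 40))
  expect_error(bias_correctness_correlation(flat),
               class = "swinecs_data_error")
  expect_error(bias_correctness_correlation(summ[1:2, ]),
               class = "swinecs_data_error")
})

test_that("latency summary computes means, ratio, and a rank-sum p-value", {
  tr <- make_trials(contrast = rep(1, 4),
                    target_side = c(1, 1, 1, 1),
                    chosen_side = c(1, 1, 2, 2),
                    latency_s = c(2, 4, 6, 12))
  ls <- latency_summary(tr)
  expect_equal(ls$mean_latency_correct_s, 3)
  expect_equal(ls$mean_latency_incorrect_s, 9)
  expect_equal(ls$ratio_incorrect_over_correct, 3)
  expect_true(ls$complete)

  # identical samples: ratio exactly 1, no evidence of a difference
  tr_same <- make_trials(contrast = rep(1, 8),
                         target_side = rep(1, 8),
                         chosen_side = rep(c(1, 2), each = 4),
                         latency_s = rep(c(3, 5, 7, 9), 2))
  ls_same <- latency_summary(tr_same)
  expect_equal(ls_same$ratio_incorrect_over_correct, 1)
  expect_gt(ls_same$test_p_value, 0.9)

  # all-correct logs: ratio undefined, flagged incomplete
  tr_ok <- make_trials(contrast = rep(1, 3), target_side = rep(1, 3),
                       chosen_side = rep(1, 3), latency_s = c(2, 3, 4))
  ls_ok <- latency_summary(tr_ok)
  expect_true(is.na(ls_ok$ratio_incorrect_over_correct))
  expect_false(ls_ok$complete)

  # Monte-Carlo: simulated 3x latency ratio is recovered from logs
  obs <- observer_params(alpha = 0.5, beta = 6, lapse = 0.02,
                         latency_median_correct_s = 8.6,
                         latency_ratio_incorrect = 3, latency_sigma = 0.4,
                         seed = 7)
  logs <- run_sessions(session_config(seed = 18), obs, 5)
  ls_sim <- latency_summary(logs)
  expect_gt(ls_sim$ratio_incorrect_over_correct, 2.5)
  expect_lt(ls_sim$ratio_incorrect_over_correct, 3.5)
  expect_lt(ls_sim$test_p_value, 1e-6)

  # t-test alternative is exposed
  expect_s3_class(latency_summary(tr, test = "t"), "latency_summary")
})

test_that("training success applies the strict >75% rule at full contrast", {
  mk <- function(k, n) {
    make_trials(contrast = rep(1, n), target_side = rep(1, n),
                chosen_side = c(rep(1, k), rep(2, n - k)))
  }
  expect_true(training_success(mk(80, 100)))
  expect_true(training_success(mk(76, 100)))
  expect_false(training_success(mk(75, 100)))
  no_full <- make_trials(contrast = rep(0.5, 10), target_side = rep(1, 10),
                         chosen_side = rep(1, 10))
  expect_error(training_success(no_full), class = "swinecs_data_error")
})

test_that("session summaries expose the training-curve quantities", {
  logs <- run_sessions(session_config(seed = 19),
                       observer_preset("good_cs"), 3)
  summ <- session_summaries(logs)
  expect_equal(nrow(summ), 3)
  expect_equal(summ$n_trials_completed, rep(100L, 3))
  expect_true(all(summ$percent_correct >= 0 & summ$percent_correct <= 100))
  expect_equal(summ$bias_magnitude, abs(summ$side1_touch_percent - 50))
})
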