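test_that("p_correct matches the closed-form mixture", {
  # logistic midpoint: unbiased, lapse-free observer is at 75% at alpha
  obs <- observer_params(alpha = 0.4, beta = 12, lapse = 0)
  expect_equal(p_correct(obs, 0.4), 0.75)

  # pure side-presser is at chance regardless of contrast
  pressy <- observer_params(alpha = 0.4, beta = 12, lapse = 0,
                            bias_strength = 1)
  expect_equal(p_correct(pressy, c(0, 0.4, 1)), rep(0.5, 3))

  # steep curve saturates at 1 far above threshold
  steep <- observer_params(alpha = 0.4, beta = 30, lapse = 0)
  expect_lt(abs(p_correct(steep, 1.0) - 1.0), 1e-6)

  # lapse caps the asymptote: (1 - b)(1 - lambda) + b/2 at high contrast
  lapsy <- observer_params(alpha = 0.1, beta = 100, lapse = 0.08)
  expect_equal(p_correct(lapsy, 1.0), 1 - 0.08, tolerance = 1e-6)

  expect_error(p_correct(obs, 1.5), class = "swinecs_config_error")
  expect_error(p_correct(obs, -0.1), class = "swinecs_config_error")
})

test_that("p_correct is monotone nondecreasing in contrast (property sweep)", {
  grid <- seq(0, 1, by = 0.01)
  set.seed(11)
  for (i in 1:40) {
    obs <- observer_params(
      alpha = runif(1, 0, 1.2),
      beta = runif(1, 0.5, 60),
      lapse = runif(1, 0, 0.1),
      bias_strength = runif(1),
      family = sample(c("logistic", "weibull"), 1))
    if (obs$family == "weibull" && obs$alpha <= 0) next
    p <- p_correct(obs, grid)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("respond reproduces bias, limit cases, and the latency ratio", {
  # full bias: every touch lands on the preferred side
  pressy <- observer_params(bias_side = 2, bias_strength = 1)
  set.seed(1)
  sides <- replicate(100, respond(pressy, 0.5, sample(1:2, 1))$chosen_side)
  expect_true(all(sides == 2))

  # perfect observer always picks the target
  perfect <- observer_preset("perfect")
  set.seed(2)
  ok <- replicate(200, {
    tgt <- sample(1:2, 1)
    respond(perfect, 0.5, tgt)$chosen_side == tgt
  })
  expect_true(all(ok))

  # Monte-Carlo: median incorrect latency ~ 3x median correct latency
  obs <- observer_params(alpha = 0.5, beta = 5, lapse = 0.02,
                         latency_median_correct_s = 8.6,
                         latency_ratio_incorrect = 3, latency_sigma = 0.4)
  set.seed(3)
  n <- 10000
  lat <- numeric(n)
  correct <- logical(n)
  for (i in seq_len(n)) {
    tgt <- if (i %% 2 == 0) 1L else 2L
    r <- respond(obs, 0.3, tgt)
    lat[i] <- r$latency_s
    correct[i] <- r$chosen_side == tgt
  }
  ratio <- median(lat[!correct]) / median(lat[correct])
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 3.2)
})

test_that("unbiased side choices are balanced over counterbalanced targets", {
  obs <- observer_params(alpha = 0.4, beta = 10, lapse = 0.02,
                         bias_strength = 0, fatigue_trials = 100)
  log <- run_session(session_config(seed = 21), obs)
  p1 <- mean(log$trials$chosen_side == 1)
  n <- nrow(log$trials)
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(p1, ci[1])
  expect_lte(p1, ci[2])
})

test_that("advance_session raises the slope and a learner improves", {
  obs <- observer_params(learning_rate = 0)
  expect_identical(advance_session(obs), obs)

  learner <- observer_preset("learner")
  # p_correct at a supra-threshold contrast is nondecreasing over sessions
  p_by_session <- vapply(0:5, function(s) {
    o <- learner
    for (i in seq_len(s)) o <- advance_session(o)
    p_correct(o, 1.0)
  }, 0)
  expect_true(all(diff(p_by_session) >= 0))

  # simulated: session 6 beats session 1 at the full-contrast target
  cfg <- session_config("self_run_training", reps_per_contrast = 80L,
                        max_trials = 80L, seed = 9)
  logs <- run_sessions(cfg, learner, 6)
  pc <- session_summaries(logs)$percent_correct
  expect_gt(pc[6], pc[1])
})

test_that("observer JSON round-trips and presets ship valid parameters", {
  for (nm in c("perfect", "good_cs", "weak_cs", "biased", "learner",
               "random")) {
    obs <- observer_preset(nm)
    expect_s3_class(obs, "observer_params")
    expect_equal(obs$guess, 0.5)
  }
  obs <- observer_params(alpha = 0.37, beta = 9, lapse = 0.03,
                         bias_side = 2, bias_strength = 0.25, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  observer_to_json(obs, path)
  expect_equal(observer_from_json(path), obs)
  expect_error(observer_params(lapse = 0.5), class = "swinecs_config_error")
  expect_error(observer_params(beta = -1), class = "swinecs_config_error")
})
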