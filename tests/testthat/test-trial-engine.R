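test_that("session_config enforces phase/level pairings and flags odd sizes", {
  cfg <- session_config()
  expect_equal(cfg$contrast_levels, seq(0.1, 1, by = 0.1))
  expect_equal(session_config("self_run_training")$contrast_levels, 1.0)
  expect_error(session_config("self_run_training",
                              contrast_levels = c(0.5, 1)),
               class = "swinecs_config_error")
  expect_error(session_config("experiment", contrast_levels = c(0.5, 1)),
               class = "swinecs_config_error")
  expect_error(session_config(contrast_levels = numeric(0)),
               class = "swinecs_config_error")
  expect_warning(session_config("self_run_training", reps_per_contrast = 30L,
                                max_trials = 30L),
                 "50-100")
})

test_that("schedules are complete, counterbalanced, and seed-reproducible", {
  # 10 levels x 10 reps -> 100 trials, each contrast exactly 10 times
  sched <- make_schedule(session_config(seed = 4))
  expect_equal(nrow(sched), 100)
  expect_true(all(table(sched$contrast) == 10))
  # counterbalanced: 5 presentations per side within every contrast
  tab <- table(sched$contrast, sched$target_side)
  expect_true(all(tab == 5))

  # single level, 50 reps -> 25 trials per side
  cfg1 <- session_config("self_run_training", reps_per_contrast = 50L,
                         max_trials = 50L, seed = 8)
  s1 <- make_schedule(cfg1)
  expect_equal(unname(c(table(s1$target_side))), c(25, 25))

  # determinism and truncation
  expect_identical(make_schedule(session_config(seed = 4)), sched)
  cfg_tr <- session_config(reps_per_contrast = 10L, max_trials = 60L,
                           seed = 4)
  expect_equal(nrow(make_schedule(cfg_tr)), 60)
})

test_that("iid side assignment is available as an alternative", {
  cfg <- session_config(seed = 30, iid_sides = TRUE)
  scheds <- lapply(30:39, function(s) {
    make_schedule(session_config(seed = s, iid_sides = TRUE))
  })
  per_side <- vapply(scheds, function(s) sum(s$target_side == 1), 0L)
  # iid flips are not forced to the exact counterbalanced split every time
  expect_true(any(per_side != 50))
})

test_that("the engine requires a full mat cycle and ignores invalid touches", {
  cfg <- session_config(seed = 2)
  sched <- make_schedule(cfg)
  eng <- trial_engine(sched, cfg)

  # touch before any arming mat cycle: ignored, no trial consumed
  expect_null(run_trial(eng, touch_event(1, 2.0)))
  expect_equal(eng$next_trial, 1L)

  mat_step(eng, "off")
  mat_step(eng, "on")
  # sub-threshold contact area: ignored, trial still pending
  expect_null(run_trial(eng, touch_event(1, 2.0, valid = FALSE)))
  expect_true(eng$armed)

  rec <- run_trial(eng, touch_event(sched$target_side[1], 2.5))
  expect_true(rec$correct)
  expect_true(rec$rewarded)
  expect_equal(rec$latency_s, 2.5)
  expect_false(eng$armed)

  # standing on the mat does not re-arm without stepping off first
  mat_step(eng, "on")
  expect_null(run_trial(eng, touch_event(1, 1.0)))

  mat_step(eng, "off")
  mat_step(eng, "on")
  wrong <- 3L - sched$target_side[2]
  rec2 <- run_trial(eng, touch_event(wrong, 4.0))
  expect_false(rec2$correct)
  expect_false(rec2$rewarded)

  # timeout: aborted, no choice, no reward
  mat_step(eng, "off")
  mat_step(eng, "on")
  rec3 <- run_trial(eng, NULL)
  expect_true(rec3$aborted)
  expect_true(is.na(rec3$chosen_side))
  expect_true(is.na(rec3$correct))
  expect_false(rec3$rewarded)
})

test_that("run_session honors fatigue, rewards correct trials, reproduces", {
  cfg <- session_config(seed = 5)
  tired <- observer_params(alpha = 0.3, beta = 15, fatigue_trials = 60L)
  log <- run_session(cfg, tired)
  expect_equal(nrow(log$trials), 60)

  # conservation: rewards dispensed == correct trials
  expect_equal(sum(log$trials$rewarded),
               sum(log$trials$correct, na.rm = TRUE))

  # perfect observer completes a 100-trial session at 100%
  plog <- run_session(cfg, observer_preset("perfect"))
  expect_equal(nrow(plog$trials), 100)
  expect_true(all(plog$trials$correct))
  expect_equal(sum(plog$trials$rewarded), 100)

  # bit-identical reproduction from the same seed pair
  expect_identical(run_session(cfg, tired), log)
})

test_that("response timeouts abort trials and are excluded downstream", {
  cfg <- session_config(seed = 6, response_timeout_s = 10)
  slow <- observer_params(alpha = 0.3, beta = 15,
                          latency_median_correct_s = 9,
                          latency_ratio_incorrect = 3, latency_sigma = 0.5)
  log <- run_session(cfg, slow)
  ab <- log$trials$aborted
  expect_gt(sum(ab), 0)
  expect_true(all(is.na(log$trials$chosen_side[ab])))
  expect_true(all(!log$trials$rewarded[ab]))
  expect_true(all(log$trials$latency_s[!ab] <= 10))
  pc <- per_contrast_performance(log)
  expect_equal(sum(pc$n), sum(!ab))
})

test_that("schedule invariants hold across seeds (property sweep)", {
  for (seed in 1:25) {
    sched <- make_schedule(session_config(seed = seed))
    expect_true(all(table(sched$contrast) == 10))
    expect_true(all(table(sched$contrast, sched$target_side) == 5))
    expect_equal(sched$trial_index, 1:100)
  }
})
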