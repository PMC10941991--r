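# The trial protocol as a state machine: weight-mat arming (step off, step
# back on), two-panel stimulus display, touch classification, reward
# contingency, and session termination by schedule end or observer fatigue.

#' Session configuration
#'
#' Describes one session of the touchscreen protocol. Phases mirror the
#' training sequence: `operator_training` (operator-guided, full-contrast
#' target only), `self_run_training` (animal self-runs, full-contrast target
#' only), and `experiment` (the ten-level contrast set presented in random
#' order, each level a fixed number of times).
#'
#' @param phase one of `"experiment"`, `"self_run_training"`,
#'   `"operator_training"`.
#' @param contrast_levels contrast fractions presented. Defaults to the
#'   standard ten levels for `experiment` and `1.0` alone for the training
#'   phases; training phases require exactly `c(1)` and `experiment`
#'   requires the ten standard levels.
#' @param reps_per_contrast presentations per contrast level (default 10).
#' @param max_trials session cap. Sessions normally hold 50-100 trials;
#'   values outside that range are accepted with a warning.
#' @param seed integer seed; the schedule sub-stream is derived from it.
#' @param mean_luminance,spatial_frequency stimulus rendering parameters,
#'   shared by target and control (see [stimulus_spec()]).
#' @param response_timeout_s seconds allowed from screen activation to
#'   touch, or `NULL` (default) to wait indefinitely; timed-out trials are
#'   recorded as aborted and excluded from performance denominators.
#' @param iid_sides if `TRUE`, target sides are independent fair coin
#'   flips; the default `FALSE` counterbalances sides within each contrast
#'   level before shuffling, so side bias is identifiable from short
#'   sessions.
#' @return an object of class `session_config`.
#' @export
#' @examples
#' session_config()                        # standard experimental session
#' session_config("self_run_training", reps_per_contrast = 60)
session_config <- function(phase = c("experiment", "self_run_training",
                                     "operator_training"),
                           contrast_levels = NULL,
                           reps_per_contrast = 10L,
                           max_trials = 100L,
                           seed = 1L,
                           mean_luminance = 127.5,
                           spatial_frequency = 8L,
                           response_timeout_s = NULL,
                           iid_sides = FALSE) {
  phase <- match.arg(phase)
  standard <- seq(0.1, 1.0, by = 0.1)
  if (is.null(contrast_levels)) {
    contrast_levels <- if (phase == "experiment") standard else 1.0
  }
  if (!is.numeric(contrast_levels) || length(contrast_levels) == 0) {
    stop_config("contrast_levels must be a non-empty numeric vector")
  }
  if (anyNA(contrast_levels) ||
      any(contrast_levels < 0 | contrast_levels > 1)) {
    stop_config("contrast_levels must lie in [0, 1]")
  }
  if (anyDuplicated(contrast_levels)) {
    stop_config("contrast_levels must be distinct")
  }
  if (phase %in% c("self_run_training", "operator_training") &&
      !identical(as.numeric(contrast_levels), 1.0)) {
    stop_config("training phases present only the 100%% contrast target")
  }
  if (phase == "experiment" &&
      !isTRUE(all.equal(sort(as.numeric(contrast_levels)), standard))) {
    stop_config("the experiment phase uses the standard 10-level contrast set")
  }
  if (!is_count(reps_per_contrast)) {
    stop_config("reps_per_contrast must be a positive integer")
  }
  if (!is_count(max_trials)) {
    stop_config("max_trials must be a positive integer")
  }
  if (max_trials < 50 || max_trials > 100) {
    warning("max_trials outside the typical 50-100 trial session range",
            call. = FALSE)
  }
  if (!is_scalar_number(seed) || seed != trunc(seed)) {
    stop_config("seed must be a single integer")
  }
  if (!is.null(response_timeout_s) &&
      (!is_scalar_number(response_timeout_s) || response_timeout_s <= 0)) {
    stop_config("response_timeout_s must be positive or NULL")
  }
  structure(
    list(phase = phase,
         contrast_levels = as.numeric(contrast_levels),
         reps_per_contrast = as.integer(reps_per_contrast),
         max_trials = as.integer(max_trials),
         seed = as.integer(seed),
         mean_luminance = mean_luminance,
         spatial_frequency = as.integer(spatial_frequency),
         response_timeout_s = response_timeout_s,
         iid_sides = isTRUE(iid_sides)),
    class = "session_config")
}

#' Build the trial schedule for a session
#'
#' Each contrast level appears `reps_per_contrast` times with target sides
#' counterbalanced within the level (an odd repetition count assigns the
#' leftover presentation to a random side); the full list is then shuffled
#' as one seeded permutation and truncated to `max_trials`. With
#' `iid_sides = TRUE` sides are instead independent fair coin flips.
#' Identical configurations (including seed) reproduce identical schedules.
#'
#' @param config a [session_config()].
#' @return data frame with columns `trial_index`, `contrast`,
#'   `target_side` (1 = left panel, 2 = right panel).
#' @export
#' @examples
#' sched <- make_schedule(session_config(seed = 7))
#' table(sched$contrast)  # each of the 10 levels exactly 10 times
make_schedule <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed(derive_seed(config$seed, "schedule"), {
    rows <- lapply(config$contrast_levels, function(ct) {
      r <- config$reps_per_contrast
      sides <- if (config$iid_sides) {
        sample(c(1L, 2L), r, replace = TRUE)
      } else {
        half <- r %/% 2
        s <- c(rep(1L, half), rep(2L, half))
        if (r %% 2 == 1) s <- c(s, sample(c(1L, 2L), 1))
        s
      }
      data.frame(contrast = ct, target_side = sides)
    })
    full <- do.call(rbind, rows)
    full <- full[sample(nrow(full)), , drop = FALSE]
    n <- min(config$max_trials, nrow(full))
    full <- full[seq_len(n), , drop = FALSE]
    data.frame(trial_index = seq_len(n),
               contrast = full$contrast,
               target_side = full$target_side)
  })
}

#' Create a trial engine for a schedule
#'
#' The engine holds the protocol state: it must be armed by a full
#' weight-mat cycle (step off, then step back on) before a touch counts,
#' mirroring the physical rule that guarantees the animal is oriented
#' toward the screen when the trial clock starts. Touches while disarmed,
#' and touches below the minimum contact-area threshold
#' (`valid = FALSE`), are ignored.
#'
#' @param schedule a schedule from [make_schedule()].
#' @param config the [session_config()] the schedule was built from.
#' @return a `trial_engine` object (an environment).
#' @seealso [mat_step()], [run_trial()]
#' @export
trial_engine <- function(schedule, config) {
  stopifnot(is.data.frame(schedule), inherits(config, "session_config"))
  e <- new.env(parent = emptyenv())
  e$contrast <- schedule$contrast
  e$target_side <- schedule$target_side
  e$trial_index <- schedule$trial_index
  e$n <- nrow(schedule)
  e$config <- config
  e$next_trial <- 1L
  e$armed <- FALSE
  e$off_since_last <- TRUE # animal approaches the mat fresh
  e$rewards <- 0L
  class(e) <- "trial_engine"
  e
}

#' Register a weight-mat event
#'
#' Stepping off the mat and back on arms the next trial (activates the
#' screen); stepping on without an intervening step-off, or while a trial
#' is pending, does nothing.
#'
#' @param engine a [trial_engine()].
#' @param action `"off"` or `"on"`.
#' @return the engine, invisibly.
#' @export
mat_step <- function(engine, action = c("on", "off")) {
  stopifnot(inherits(engine, "trial_engine"))
  action <- match.arg(action)
  if (action == "off") {
    engine$off_since_last <- TRUE
  } else if (engine$off_since_last && !engine$armed &&
             engine$next_trial <= engine$n) {
    engine$armed <- TRUE
    engine$off_since_last <- FALSE
  }
  invisible(engine)
}

#' A touch event on the two-panel screen
#'
#' @param side touched panel, 1 or 2.
#' @param time_s seconds from screen activation to touch (the latency).
#' @param valid `FALSE` for contacts below the minimum surface-area
#'   threshold of the touchscreen, which the engine ignores.
#' @return a `touch_event` list.
#' @export
touch_event <- function(side, time_s = NA_real_, valid = TRUE) {
  stopifnot(side %in% c(1, 2))
  structure(list(side = as.integer(side), time_s = time_s,
                 valid = isTRUE(valid)),
            class = "touch_event")
}

#' Run one trial through the engine
#'
#' If the engine is armed, classifies the touch against the scheduled
#' target side: a touch on the target panel is correct and dispenses a
#' reward; a touch on the control panel ends the trial without reward.
#' `touch = NULL` records a timed-out (aborted) trial: no chosen side, no
#' outcome, no reward. Invalid touches and touches while disarmed are
#' ignored and return `NULL` (no trial is consumed).
#'
#' @param engine a [trial_engine()].
#' @param touch a [touch_event()], or `NULL` for a response timeout.
#' @return a one-trial record (list), or `NULL` for an ignored touch.
#' @export
run_trial <- function(engine, touch) {
  stopifnot(inherits(engine, "trial_engine"))
  if (!engine$armed) return(invisible(NULL))
  if (!is.null(touch)) {
    stopifnot(inherits(touch, "touch_event"))
    if (!touch$valid) return(invisible(NULL)) # below contact threshold
  }
  i <- engine$next_trial
  if (is.null(touch)) {
    rec <- list(trial_index = engine$trial_index[i],
                contrast = engine$contrast[i],
                target_side = engine$target_side[i],
                chosen_side = NA_integer_, correct = NA,
                latency_s = NA_real_, rewarded = FALSE, aborted = TRUE)
  } else {
    correct <- touch$side == engine$target_side[i]
    if (correct) engine$rewards <- engine$rewards + 1L
    rec <- list(trial_index = engine$trial_index[i],
                contrast = engine$contrast[i],
                target_side = engine$target_side[i],
                chosen_side = touch$side, correct = correct,
                latency_s = touch$time_s, rewarded = correct,
                aborted = FALSE)
  }
  engine$armed <- FALSE
  engine$next_trial <- i + 1L
  rec
}

#' Simulate a full session
#'
#' Builds the seeded schedule, then walks the engine through mat cycles,
#' querying the simulated observer for each armed trial, until the
#' schedule is exhausted or the observer's fatigue point is reached.
#' The schedule is driven by the config's seed and the behavior by the
#' observer's seed (independent derived sub-streams), so the whole log is
#' bit-reproducible from the pair.
#'
#' @param config a [session_config()].
#' @param observer an [observer_params()].
#' @param animal_id identifier recorded in the log.
#' @param session_date a `Date` recorded in the log.
#' @return an object of class `session_log`: a list with `animal_id`,
#'   `session_date`, `config`, and `trials` (one row per trial).
#' @export
#' @examples
#' log <- run_session(session_config(seed = 3), observer_preset("good_cs"))
#' head(log$trials)
run_session <- function(config, observer,
                        animal_id = "sim1",
                        session_date = as.Date("2023-11-01")) {
  stopifnot(inherits(config, "session_config"),
            inherits(observer, "observer_params"))
  schedule <- make_schedule(config)
  n_sched <- nrow(schedule)
  n_run <- if (is.null(observer$fatigue_trials)) n_sched else
    min(n_sched, observer$fatigue_trials)
  engine <- trial_engine(schedule, config)
  timeout <- config$response_timeout_s

  chosen <- integer(n_run)
  correct <- logical(n_run)
  latency <- numeric(n_run)
  rewarded <- logical(n_run)
  aborted <- logical(n_run)

  with_seed(derive_seed(observer$seed, "observer"), {
    for (i in seq_len(n_run)) {
      mat_step(engine, "off")
      mat_step(engine, "on")
      resp <- respond(observer, schedule$contrast[i], schedule$target_side[i])
      touch <- if (!is.null(timeout) && resp$latency_s > timeout) NULL else
        touch_event(resp$chosen_side, time_s = resp$latency_s)
      rec <- run_trial(engine, touch)
      chosen[i] <- rec$chosen_side
      correct[i] <- rec$correct
      latency[i] <- rec$latency_s
      rewarded[i] <- rec$rewarded
      aborted[i] <- rec$aborted
    }
  })

  trials <- data.frame(
    trial_index = schedule$trial_index[seq_len(n_run)],
    contrast = schedule$contrast[seq_len(n_run)],
    target_side = schedule$target_side[seq_len(n_run)],
    chosen_side = ifelse(aborted, NA_integer_, chosen),
    correct = ifelse(aborted, NA, correct),
    latency_s = ifelse(aborted, NA_real_, latency),
    rewarded = rewarded,
    aborted = aborted)
  structure(list(animal_id = animal_id,
                 session_date = as.Date(session_date),
                 config = config,
                 trials = trials),
            class = "session_log")
}

#' Simulate a sequence of sessions with learning
#'
#' Runs `n_sessions` sessions, deriving fresh schedule and observer
#' sub-seeds per session from the top-level seeds and applying
#' [advance_session()] between sessions so a learner's slope grows over
#' the training period. Session dates advance by `session_interval_days`
#' (default 3, matching a cadence of at most three test days per week).
#'
#' @param config a [session_config()].
#' @param observer an [observer_params()].
#' @param n_sessions number of sessions.
#' @param animal_id identifier recorded in the logs.
#' @param start_date date of the first session.
#' @param session_interval_days days between consecutive sessions.
#' @return list of [run_session()] logs.
#' @export
run_sessions <- function(config, observer, n_sessions,
                         animal_id = "sim1",
                         start_date = as.Date("2023-11-01"),
                         session_interval_days = 3L) {
  stopifnot(is_count(n_sessions))
  logs <- vector("list", n_sessions)
  obs <- observer
  for (i in seq_len(n_sessions)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, sprintf("session-%d", i))
    obs_i <- obs
    obs_i$seed <- derive_seed(observer$seed, sprintf("session-%d", i))
    logs[[i]] <- run_session(
      cfg_i, obs_i, animal_id = animal_id,
      session_date = as.Date(start_date) + (i - 1L) * session_interval_days)
    obs <- advance_session(obs)
  }
  logs
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "<session_config> phase %s: %d contrast level(s) x %d reps, max %d trials, seed %d\n",
    x$phase, length(x$contrast_levels), x$reps_per_contrast, x$max_trials,
    x$seed))
  invisible(x)
}

#' @export
print.session_log <- function(x, ...) {
  tr <- x$trials
  done <- !tr$aborted
  pc <- if (any(done)) 100 * mean(tr$correct[done]) else NA_real_
  cat(sprintf(
    "<session_log> %s %s (%s): %d trials (%d aborted), %.1f%% correct, %d rewards\n",
    x$animal_id, format(x$session_date), x$config$phase, nrow(tr),
    sum(tr$aborted), pc, sum(tr$rewarded)))
  invisible(x)
}
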