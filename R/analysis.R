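# Analysis chain: everything reported from the behavioral logs --
# per-contrast performance against chance, side bias, the bias-accuracy
# rank correlation, latency by outcome, the training-success criterion, and
# session summaries. Aborted (timed-out) trials are excluded from every
# performance denominator.

# Accepts a single session_log, a list of them, or an already-combined
# trials data frame; returns one data frame with a session id column.
as_trials <- function(logs) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (is.data.frame(logs)) {
    if (!"session" %in% names(logs)) logs$session <- 1L
    return(logs)
  }
  if (!is.list(logs) || length(logs) == 0) {
    stop_data("expected a session_log, a list of them, or a trials data frame")
  }
  parts <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    stopifnot(inherits(log, "session_log"))
    cbind(data.frame(session = i,
                     animal_id = log$animal_id,
                     session_date = format(log$session_date, "%Y-%m-%d"),
                     stringsAsFactors = FALSE),
          log$trials)
  })
  do.call(rbind, parts)
}

completed_trials <- function(logs) {
  tr <- as_trials(logs)
  tr[!tr$aborted, , drop = FALSE]
}

#' Two-sided exact binomial test against 50:50 chance
#'
#' Probability, under a fair-coin null, of an outcome at most as likely as
#' the observed number of correct choices (the minimum-likelihood
#' two-sided rule of [stats::binom.test()]). This is the test applied to
#' each contrast level's correct-response count; with a symmetric null it
#' equals the doubled tail, e.g. 10/10 correct gives `2 * 0.5^10`.
#'
#' @param k number of correct trials.
#' @param n number of trials.
#' @return two-sided exact p-value.
#' @export
#' @examples
#' binomial_vs_chance(10, 10)  # 0.001953125
#' binomial_vs_chance(5, 10)   # 1
binomial_vs_chance <- function(k, n) {
  if (!is_scalar_number(n) || n < 1 || n != trunc(n)) {
    stop_config("n must be a positive integer")
  }
  if (!is_scalar_number(k) || k < 0 || k > n || k != trunc(k)) {
    stop_config("k must be an integer in [0, n]")
  }
  stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
}

#' Per-contrast performance pooled across sessions
#'
#' Counts non-aborted presentations and correct choices per distinct
#' contrast level, pooling all supplied sessions, and attaches the exact
#' binomial p-value against chance for each level. Contrast levels with no
#' completed presentations are omitted with a warning.
#'
#' @param logs session log(s) (see [run_session()], [read_session_logs()]).
#' @return data frame with columns `contrast`, `n`, `k`, `percent_correct`,
#'   `p_value_vs_chance`, ordered by contrast.
#' @export
per_contrast_performance <- function(logs) {
  tr <- as_trials(logs)
  levels_all <- sort(unique(tr$contrast))
  tr <- tr[!tr$aborted, , drop = FALSE]
  if (nrow(tr) == 0) stop_data("no completed trials to analyze")
  dropped <- setdiff(levels_all, unique(tr$contrast))
  if (length(dropped)) {
    warning(sprintf("contrast level(s) with no completed trials omitted: %s",
                    paste(format(dropped), collapse = ", ")), call. = FALSE)
  }
  contrasts <- sort(unique(tr$contrast))
  n <- vapply(contrasts, function(ct) sum(tr$contrast == ct), 0L)
  k <- vapply(contrasts, function(ct) {
    sum(tr$correct[tr$contrast == ct])
  }, 0L)
  data.frame(
    contrast = contrasts,
    n = n,
    k = k,
    percent_correct = 100 * k / n,
    p_value_vs_chance = vapply(seq_along(n), function(i) {
      binomial_vs_chance(k[i], n[i])
    }, 0))
}

#' Screen-side touch bias
#'
#' Percentage of completed trials touched on side 1 (left panel). Touches
#' near 50% indicate no side preference; a minority side below 25% flags a
#' significant screen-side bias.
#'
#' @param logs session log(s).
#' @return list with `side1_touch_percent`, `side2_touch_percent`,
#'   `biased` (logical), and `n`.
#' @export
#' @examples
#' side_bias(run_session(session_config(seed = 2), observer_preset("biased")))
side_bias <- function(logs) {
  tr <- completed_trials(logs)
  if (nrow(tr) == 0) stop_data("side bias undefined: no completed trials")
  p1 <- 100 * mean(tr$chosen_side == 1)
  list(side1_touch_percent = p1,
       side2_touch_percent = 100 - p1,
       biased = min(p1, 100 - p1) < 25,
       n = nrow(tr))
}

#' Per-session summaries (training-curve view)
#'
#' One row per session: overall percent correct, side-1 touch percentage
#' and its bias magnitude `|side1% - 50|`, completed-trial count, and mean
#' latencies by outcome.
#'
#' @param logs a list of session logs (or a single log).
#' @return data frame with one row per session.
#' @export
session_summaries <- function(logs) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  stopifnot(is.list(logs), length(logs) > 0)
  rows <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    tr <- log$trials[!log$trials$aborted, , drop = FALSE]
    if (nrow(tr) == 0) {
      stop_data("session %d has no completed trials", i)
    }
    p1 <- 100 * mean(tr$chosen_side == 1)
    lat_c <- tr$latency_s[tr$correct & !is.na(tr$latency_s)]
    lat_i <- tr$latency_s[!tr$correct & !is.na(tr$latency_s)]
    data.frame(
      session = i,
      animal_id = log$animal_id,
      session_date = format(log$session_date, "%Y-%m-%d"),
      phase = log$config$phase,
      n_trials_completed = nrow(tr),
      n_aborted = sum(log$trials$aborted),
      percent_correct = 100 * mean(tr$correct),
      side1_touch_percent = p1,
      bias_magnitude = abs(p1 - 50),
      mean_latency_correct_s = if (length(lat_c)) mean(lat_c) else NA_real_,
      mean_latency_incorrect_s = if (length(lat_i)) mean(lat_i) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation between side bias and accuracy
#'
#' Rank correlation between per-session percent correct and per-session
#' bias magnitude `|side1_touch_percent - 50|`. A strong negative rho
#' reproduces the coupling in which drifting onto one screen side goes
#' with falling accuracy. The p-value is exact when there are no ties and
#' the asymptotic t approximation otherwise (the convention of
#' [stats::cor.test()]).
#'
#' @param x either the data frame from [session_summaries()] or a list of
#'   session logs (at least 3 sessions).
#' @return list with `rho`, `p_value`, `n_sessions`.
#' @export
bias_correctness_correlation <- function(x) {
  summ <- if (is.data.frame(x)) x else session_summaries(x)
  if (!all(c("percent_correct", "bias_magnitude") %in% names(summ))) {
    stop_data("need columns percent_correct and bias_magnitude")
  }
  if (nrow(summ) < 3) stop_data("need at least 3 sessions")
  pc <- summ$percent_correct
  bm <- summ$bias_magnitude
  if (stats::sd(pc) == 0 || stats::sd(bm) == 0) {
    stop_data("correlation undefined: an input vector is constant")
  }
  ct <- suppressWarnings(
    stats::cor.test(pc, bm, method = "spearman", exact = NULL))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_sessions = nrow(summ))
}

#' Latency summary by outcome
#'
#' Mean latency (screen activation to screen touch) for correct and
#' incorrect completed trials, their ratio, and a two-sided test comparing
#' the two latency samples: Mann-Whitney/Wilcoxon rank-sum by default
#' (latencies are right-skewed), Welch t-test via `test = "t"`. With no
#' incorrect trials the ratio is undefined and flagged.
#'
#' @param logs session log(s).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return object of class `latency_summary`: a list with
#'   `mean_latency_correct_s`, `mean_latency_incorrect_s`,
#'   `ratio_incorrect_over_correct`, `test`, `test_p_value`,
#'   `n_correct`, `n_incorrect`, `complete` (logical flag).
#' @export
latency_summary <- function(logs, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  tr <- completed_trials(logs)
  tr <- tr[!is.na(tr$latency_s), , drop = FALSE]
  if (nrow(tr) == 0) stop_data("no completed trials with latencies")
  lat_c <- tr$latency_s[tr$correct]
  lat_i <- tr$latency_s[!tr$correct]
  mean_c <- if (length(lat_c)) mean(lat_c) else NA_real_
  mean_i <- if (length(lat_i)) mean(lat_i) else NA_real_
  complete <- length(lat_c) > 0 && length(lat_i) > 0
  ratio <- if (complete) mean_i / mean_c else NA_real_
  p <- if (complete) {
    if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(lat_i, lat_c)$p.value)
    } else {
      stats::t.test(lat_i, lat_c)$p.value
    }
  } else {
    NA_real_
  }
  structure(list(mean_latency_correct_s = mean_c,
                 mean_latency_incorrect_s = mean_i,
                 ratio_incorrect_over_correct = ratio,
                 test = test, test_p_value = p,
                 n_correct = length(lat_c), n_incorrect = length(lat_i),
                 complete = complete),
            class = "latency_summary")
}

#' @export
print.latency_summary <- function(x, ...) {
  cat(sprintf(
    "<latency_summary> correct %.2fs (n=%d), incorrect %.2fs (n=%d), ratio %.2f, %s p=%.3g\n",
    x$mean_latency_correct_s, x$n_correct, x$mean_latency_incorrect_s,
    x$n_incorrect, x$ratio_incorrect_over_correct, x$test, x$test_p_value))
  if (!x$complete) cat("  (incomplete: one outcome class is empty)\n")
  invisible(x)
}

#' Training-success criterion
#'
#' Training counts as successful when the animal's correct-response rate
#' on the 100%-contrast target strictly exceeds 75% (75.0% exactly fails).
#'
#' @param logs session log(s) containing 100%-contrast trials.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' # 76/100 passes, 75/100 does not
training_success <- function(logs) {
  tr <- completed_trials(logs)
  tr <- tr[tr$contrast == 1, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop_data("training success undefined: no completed 100%%-contrast trials")
  }
  100 * mean(tr$correct) > 75
}
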