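# Seeded fixture generation and the end-to-end pipeline: simulate sessions
# for a named behavioral scenario, write the logs plus a manifest with
# checksums, run the full analysis chain, and emit tidy tables, a fit, the
# band classification, and a markdown report.

fixture_scenarios <- c("perfect", "good_cs", "weak_cs", "biased",
                       "learner", "random")

#' Generate reference session logs for a behavioral scenario
#'
#' Simulates `sessions` sessions for one of the shipped observer presets
#' and writes them as session-log CSVs plus a `manifest.json` recording the
#' scenario, seeds, configuration, observer parameters, and MD5 checksums
#' of every file. Output is deterministic given `seed`: the same spec
#' always reproduces byte-identical files.
#'
#' The `learner` scenario runs the self-run training phase (100%-contrast
#' target only, the phase whose session-over-session improvement the
#' learning model emulates); every other scenario runs the ten-level
#' experimental phase.
#'
#' @param scenario one of `"perfect"`, `"good_cs"`, `"weak_cs"`,
#'   `"biased"`, `"learner"`, `"random"`.
#' @param sessions number of sessions (default 4).
#' @param seed top-level integer seed.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest as a list.
#' @export
#' @examples
#' dir <- file.path(tempdir(), "fix")
#' generate_fixtures("good_cs", sessions = 2, seed = 1, dir = dir)
#' list.files(dir)
generate_fixtures <- function(scenario, sessions = 4L, seed = 1L, dir) {
  if (!is.character(scenario) || length(scenario) != 1 ||
      !scenario %in% fixture_scenarios) {
    stop_config("unknown scenario '%s' (expected one of: %s)",
                paste(scenario, collapse = ","),
                paste(fixture_scenarios, collapse = ", "))
  }
  if (!is_count(sessions)) stop_config("sessions must be a positive integer")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  observer <- observer_preset(scenario)
  observer$seed <- derive_seed(seed, paste0("observer-", scenario))
  phase <- if (scenario == "learner") "self_run_training" else "experiment"
  config <- if (phase == "experiment") {
    session_config("experiment", seed = derive_seed(seed, "config"))
  } else {
    session_config("self_run_training", reps_per_contrast = 80L,
                   max_trials = 80L, seed = derive_seed(seed, "config"))
  }

  logs <- run_sessions(config, observer, sessions, animal_id = scenario)
  files <- character(sessions)
  for (i in seq_len(sessions)) {
    files[i] <- file.path(dir, sprintf("session_%02d.csv", i))
    write_session_log(logs[[i]], files[i])
  }
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  manifest <- list(scenario = scenario,
                   sessions = sessions,
                   seed = seed,
                   config = unclass(config),
                   observer = {
                     o <- unclass(observer)
                     o$guess <- NULL
                     o
                   },
                   files = checksums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Run the complete analysis chain on a set of session logs
#'
#' Computes per-contrast performance with exact binomial tests, per-session
#' summaries, the latency comparison, the side-bias flag, the psychometric
#' fit with thresholds, and the six-area band classification; optionally
#' writes the tidy outputs (`per_contrast.csv`, `sessions.csv`,
#' `latency.csv`, `bands.csv`, `fit.json`) to a directory.
#'
#' @param logs a list of session logs (or a single log).
#' @param out_dir optional output directory for the tidy tables.
#' @param rule a [classification_rule()].
#' @param latency_test passed to [latency_summary()].
#' @return list with components `per_contrast`, `sessions`, `latency`,
#'   `bias`, `fit`, `bands` (`fit`/`bands` are `NULL` for fewer than 3
#'   contrast levels, e.g. training-phase logs), and
#'   `bias_accuracy` (`NULL` for fewer than 3 sessions or degenerate
#'   summaries).
#' @export
analyze_sessions <- function(logs, out_dir = NULL,
                             rule = classification_rule(),
                             latency_test = "wilcoxon") {
  per_contrast <- per_contrast_performance(logs)
  sessions <- session_summaries(if (inherits(logs, "session_log"))
    list(logs) else logs)
  latency <- latency_summary(logs, test = latency_test)
  bias <- side_bias(logs)
  bias_accuracy <- tryCatch(bias_correctness_correlation(sessions),
                            swinecs_data_error = function(e) NULL)
  fit <- NULL
  bands <- NULL
  if (length(unique(per_contrast$contrast)) >= 3) {
    fit <- fit_psychometric(per_contrast)
    bands <- band_summary(per_contrast, rule)
  }
  out <- list(per_contrast = per_contrast, sessions = sessions,
              latency = latency, bias = bias,
              bias_accuracy = bias_accuracy, fit = fit, bands = bands)
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

write_analysis <- function(analysis, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(analysis$per_contrast,
                   file.path(out_dir, "per_contrast.csv"), row.names = FALSE)
  utils::write.csv(analysis$sessions,
                   file.path(out_dir, "sessions.csv"), row.names = FALSE)
  lat <- analysis$latency
  utils::write.csv(
    data.frame(mean_latency_correct_s = lat$mean_latency_correct_s,
               mean_latency_incorrect_s = lat$mean_latency_incorrect_s,
               ratio_incorrect_over_correct = lat$ratio_incorrect_over_correct,
               test = lat$test, test_p_value = lat$test_p_value,
               n_correct = lat$n_correct, n_incorrect = lat$n_incorrect),
    file.path(out_dir, "latency.csv"), row.names = FALSE)
  if (!is.null(analysis$bands)) {
    utils::write.csv(analysis$bands$points,
                     file.path(out_dir, "bands.csv"), row.names = FALSE)
  }
  if (!is.null(analysis$fit)) {
    f <- analysis$fit
    jsonlite::write_json(
      list(family = f$family, alpha_hat = f$alpha_hat,
           beta_hat = f$beta_hat, lambda_hat = f$lambda_hat,
           threshold_raw = f$threshold_raw,
           threshold_corrected = f$threshold_corrected,
           converged = f$converged, note = f$note, loglik = f$loglik),
      file.path(out_dir, "fit.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  }
  invisible(out_dir)
}

#' Simulate, analyze, classify, and report in one call
#'
#' Runs the full pipeline for one simulated animal: session simulation for
#' the given observer, the analysis chain, the band classification, a
#' markdown report summarizing the results, and (optionally) PNG figures of
#' the training curve, per-contrast performance, and the fitted
#' psychometric function.
#'
#' @param observer an [observer_params()] or a preset name.
#' @param out_dir output directory.
#' @param config a [session_config()]; default a standard experimental
#'   session.
#' @param sessions number of sessions (default 4).
#' @param seed top-level seed applied to both config and observer streams.
#' @param animal_id identifier used in logs and the report.
#' @param plots write PNG figures (default `FALSE`).
#' @return invisibly, the [analyze_sessions()] result.
#' @export
end_to_end_report <- function(observer, out_dir,
                              config = session_config(),
                              sessions = 4L, seed = 1L,
                              animal_id = "sim1", plots = FALSE) {
  if (is.character(observer)) observer <- observer_preset(observer)
  stopifnot(inherits(observer, "observer_params"),
            inherits(config, "session_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  config$seed <- derive_seed(seed, "config")
  observer$seed <- derive_seed(seed, "observer")
  logs <- run_sessions(config, observer, sessions, animal_id = animal_id)
  for (i in seq_along(logs)) {
    write_session_log(logs[[i]], file.path(out_dir,
                                           sprintf("session_%02d.csv", i)))
  }
  analysis <- analyze_sessions(logs, out_dir = out_dir)
  write_report_md(analysis, file.path(out_dir, "report.md"), animal_id)
  if (plots) {
    plot_png(file.path(out_dir, "training_curve.png"),
             function() plot_training_curve(analysis$sessions))
    plot_png(file.path(out_dir, "per_contrast.png"),
             function() plot_per_contrast(analysis$per_contrast))
    if (!is.null(analysis$fit)) {
      plot_png(file.path(out_dir, "psychometric.png"),
               function() plot_psychometric(analysis$fit))
    }
  }
  invisible(analysis)
}

write_report_md <- function(analysis, path, animal_id) {
  pc <- analysis$per_contrast
  lat <- analysis$latency
  bias <- analysis$bias
  lines <- c(
    sprintf("# Contrast-sensitivity report: %s", animal_id),
    "",
    sprintf("Sessions analyzed: %d; completed trials: %d.",
            nrow(analysis$sessions), sum(pc$n)),
    "",
    "## Per-contrast performance (vs 50:50 chance)",
    "",
    "| contrast | n | correct | % correct | exact p |",
    "|---|---|---|---|---|",
    sprintf("| %.0f%% | %d | %d | %.1f | %.4g |",
            100 * pc$contrast, pc$n, pc$k, pc$percent_correct,
            pc$p_value_vs_chance),
    "",
    "## Side bias",
    "",
    sprintf("Side-1 touches: %.1f%% (%s).", bias$side1_touch_percent,
            if (bias$biased) "BIASED: minority side below 25%"
            else "no significant side bias"),
    "",
    "## Latency",
    "",
    sprintf(
      "Mean latency %.2f s correct vs %.2f s incorrect (ratio %.2f, %s p = %.3g).",
      lat$mean_latency_correct_s, lat$mean_latency_incorrect_s,
      lat$ratio_incorrect_over_correct, lat$test, lat$test_p_value))
  if (!is.null(analysis$bias_accuracy)) {
    ba <- analysis$bias_accuracy
    lines <- c(lines, "",
               "## Bias-accuracy coupling",
               "",
               sprintf(
                 "Spearman rho between session bias magnitude and percent correct: %.3f (p = %.3g, %d sessions).",
                 ba$rho, ba$p_value, ba$n_sessions))
  }
  if (!is.null(analysis$fit)) {
    f <- analysis$fit
    corr <- if (is.na(f$threshold_corrected)) "undefined" else
      sprintf("%.1f%% contrast", 100 * f$threshold_corrected)
    lines <- c(lines, "",
               "## Psychometric fit",
               "",
               sprintf(
                 "alpha = %.3f, beta = %.2f, lambda = %.3f; guessing-corrected threshold (75%% correct): %s [%s].",
                 f$alpha_hat, f$beta_hat, f$lambda_hat, corr, f$note))
  }
  if (!is.null(analysis$bands)) {
    b <- analysis$bands$band_counts
    lines <- c(lines, "",
               "## CS-function classification",
               "",
               sprintf(
                 "Of %d points: %d good/moderate CS (A1-A2), %d weak CS (A3-A4), %d random/weak training (A5-A6).",
                 analysis$bands$n, b[["good_moderate"]], b[["weak_cs"]],
                 b[["weak_training"]]))
  }
  writeLines(lines, path)
  invisible(path)
}

plot_png <- function(path, draw, width = 900, height = 600) {
  grDevices::png(path, width = width, height = height, res = 110)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' Training-curve plot: accuracy and side touches per session
#' @param sessions data frame from [session_summaries()].
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plot_training_curve <- function(sessions) {
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(sessions$session, sessions$percent_correct, type = "b",
                 pch = 19, ylim = c(0, 100), xlab = "Session",
                 ylab = "Percent", main = "Training performance")
  graphics::lines(sessions$session, sessions$side1_touch_percent,
                  type = "b", pch = 1, lty = 2)
  graphics::abline(h = c(25, 50, 75), col = "gray70", lty = 3)
  graphics::legend("bottomleft", legend = c("% correct", "% side-1 touches"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(NULL)
}

#' Per-contrast performance plot with chance line
#' @param per_contrast data frame from [per_contrast_performance()].
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plot_per_contrast <- function(per_contrast) {
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::plot(100 * per_contrast$contrast, per_contrast$percent_correct,
                 type = "b", pch = 19, ylim = c(0, 100),
                 xlab = "Contrast (%)", ylab = "Percent correct",
                 main = "Per-contrast performance")
  graphics::abline(h = 50, col = "gray50", lty = 2)
  sig <- per_contrast$p_value_vs_chance < 0.05
  if (any(sig)) {
    graphics::text(100 * per_contrast$contrast[sig],
                   pmin(per_contrast$percent_correct[sig] + 5, 99),
                   "*", cex = 1.4)
  }
  invisible(NULL)
}

#' Fitted psychometric function over the observed points
#' @param fit a `psychometric_fit`.
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plot_psychometric <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  graphics::par(mar = c(4, 4, 2, 1))
  pts <- fit$points
  graphics::plot(100 * pts$contrast, 100 * pts$k / pts$n, pch = 19,
                 ylim = c(0, 100), xlab = "Contrast (%)",
                 ylab = "Percent correct", main = "Psychometric fit")
  grid_c <- seq(0, 1, length.out = 200)
  graphics::lines(100 * grid_c, predict_percent_correct(fit, grid_c))
  graphics::abline(h = c(50, 75), col = "gray60", lty = 3)
  if (!is.na(fit$threshold_corrected)) {
    graphics::abline(v = 100 * fit$threshold_corrected, col = "gray40",
                     lty = 2)
  }
  invisible(NULL)
}
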