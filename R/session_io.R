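# Session-log CSV dialect: one row per trial, header mandatory, UTF-8,
# "." decimal, ISO-8601 dates, lowercase true/false, empty cells for
# not-applicable fields. Logs from any touchscreen system can be converted
# to this layout and fed to the analysis chain.

log_columns <- c("animal_id", "session_date", "phase", "trial_index",
                 "contrast", "target_side", "chosen_side", "correct",
                 "latency_s", "rewarded", "aborted")

fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                   scientific = FALSE,
                                                   digits = 15))

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  out
}

parse_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))

#' Write a session log to CSV
#'
#' One row per trial with columns
#' `animal_id,session_date,phase,trial_index,contrast,target_side,chosen_side,correct,latency_s,rewarded,aborted`;
#' booleans as lowercase `true`/`false`, not-applicable fields (aborted
#' trials' choice, outcome, latency) empty, dates in ISO-8601.
#'
#' @param log a `session_log` from [run_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  out <- data.frame(
    animal_id = log$animal_id,
    session_date = format(log$session_date, "%Y-%m-%d"),
    phase = log$config$phase,
    trial_index = tr$trial_index,
    contrast = fmt_num(tr$contrast),
    target_side = tr$target_side,
    chosen_side = fmt_num(tr$chosen_side),
    correct = fmt_bool(tr$correct),
    latency_s = fmt_num(tr$latency_s),
    rewarded = fmt_bool(tr$rewarded),
    aborted = fmt_bool(tr$aborted),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a session log from CSV
#'
#' Parses the dialect written by [write_session_log()]. The embedded
#' configuration is reconstructed minimally (phase and the distinct
#' contrast levels); logs converted from real touchscreen systems,
#' including operator-guided training sessions, are accepted as long as
#' the column layout matches.
#'
#' @param path CSV file path.
#' @return a `session_log`.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop_data("log file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(log_columns, names(raw))
  if (length(missing_cols)) {
    stop_data("log %s lacks column(s): %s", path,
              paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) stop_data("log %s contains no trials", path)
  phase <- unique(raw$phase)
  if (length(phase) != 1) stop_data("log %s mixes phases", path)
  contrast <- parse_num(raw$contrast)
  levels_seen <- sort(unique(contrast))
  cfg <- suppressWarnings(session_config(
    phase = phase,
    contrast_levels = if (phase == "experiment") NULL else 1.0,
    max_trials = max(nrow(raw), 1L)))
  trials <- data.frame(
    trial_index = as.integer(raw$trial_index),
    contrast = contrast,
    target_side = as.integer(raw$target_side),
    chosen_side = as.integer(parse_num(raw$chosen_side)),
    correct = parse_bool(raw$correct),
    latency_s = parse_num(raw$latency_s),
    rewarded = parse_bool(raw$rewarded),
    aborted = parse_bool(raw$aborted))
  if (any(is.na(trials$aborted))) {
    stop_data("log %s: 'aborted' must be true/false on every row", path)
  }
  if (!all(diff(trials$trial_index) == 1) || trials$trial_index[1] != 1) {
    stop_data("log %s: trial indices must be contiguous from 1", path)
  }
  bad <- !trials$aborted & (trials$rewarded != (trials$correct %in% TRUE))
  if (any(bad, na.rm = TRUE)) {
    stop_data("log %s: reward flags inconsistent with outcomes", path)
  }
  attr(cfg, "levels_seen") <- levels_seen
  structure(list(animal_id = raw$animal_id[1],
                 session_date = as.Date(raw$session_date[1]),
                 config = cfg,
                 trials = trials),
            class = "session_log")
}

#' Read every session-log CSV in a directory
#'
#' @param dir directory containing `*.csv` session logs.
#' @param animal_id optional filter: keep only logs for this animal.
#' @return list of `session_log` objects, ordered by session date.
#' @export
read_session_logs <- function(dir, animal_id = NULL) {
  if (!dir.exists(dir)) stop_data("log directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop_data("no .csv session logs in %s", dir)
  logs <- lapply(files, read_session_log)
  if (!is.null(animal_id)) {
    logs <- Filter(function(l) l$animal_id == animal_id, logs)
    if (!length(logs)) stop_data("no logs for animal '%s' in %s",
                                 animal_id, dir)
  }
  logs[order(vapply(logs, function(l) as.numeric(l$session_date), 0))]
}

#' Write a session configuration to JSON
#' @param config a [session_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
config_to_json <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session configuration from JSON
#' @param path JSON file with fields matching [session_config()] arguments.
#' @return a [session_config()].
#' @export
config_from_json <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(session_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_config("unknown config fields: %s", paste(unknown, collapse = ", "))
  }
  do.call(session_config, raw)
}
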