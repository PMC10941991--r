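# Independent oracles and small builders used across the suite.

# Brute-force two-sided exact binomial p-value under a fair-coin null:
# total probability of every outcome at most as likely as the observed one,
# by full enumeration of the n + 1 outcomes.
enum_binom_p <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Hand-built trials table in the analysis layer's column layout.
make_trials <- function(contrast, target_side, chosen_side,
                        latency_s = NA_real_, aborted = FALSE) {
  n <- length(contrast)
  aborted <- rep_len(aborted, n)
  latency_s <- rep_len(latency_s, n)
  correct <- ifelse(aborted, NA, chosen_side == target_side)
  data.frame(
    trial_index = seq_len(n),
    contrast = contrast,
    target_side = rep_len(target_side, n),
    chosen_side = ifelse(aborted, NA_integer_, chosen_side),
    correct = correct,
    latency_s = ifelse(aborted, NA_real_, latency_s),
    rewarded = correct %in% TRUE,
    aborted = aborted)
}

# Minimal session_log wrapper around a trials table.
make_log <- function(trials, phase = "experiment", animal_id = "unit",
                     session_date = as.Date("2023-11-01")) {
  cfg <- suppressWarnings(session_config(
    phase = phase,
    max_trials = max(50L, nrow(trials))))
  structure(list(animal_id = animal_id, session_date = session_date,
                 config = cfg, trials = trials),
            class = "session_log")
}
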