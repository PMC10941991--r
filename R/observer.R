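# The simulated observer: a parametric animal whose choices and latencies
# carry the behavioral structure seen in operant touchscreen work --
# contrast-dependent accuracy, screen-side bias, slower incorrect responses,
# fatigue after 50-100 trials, and session-over-session learning.

#' Parameters of the simulated observer
#'
#' The observer's probability of choosing the target panel at contrast `c`
#' (with sides counterbalanced) is
#' \deqn{p(c) = (1 - b)\,[\gamma + (1 - \gamma - \lambda) F(c)] + b/2,}
#' where \eqn{F} is a logistic `1 / (1 + exp(-beta (c - alpha)))` (or a
#' Weibull `1 - exp(-(c/alpha)^beta)`), \eqn{\gamma = 0.5} is the guess rate
#' fixed by the two-choice design, \eqn{\lambda} the lapse rate, and
#' \eqn{b} the side-bias strength: with probability `b` the animal touches
#' its preferred panel regardless of the stimulus, which couples strong
#' bias to chance-level accuracy. Latencies are log-normal with one median
#' for correct and a `latency_ratio_incorrect`-fold longer median for
#' incorrect responses.
#'
#' Learning is modeled as a per-session increment to the slope `beta`
#' (sharper detection with practice); fatigue as a hard stop after
#' `fatigue_trials` trials, matching sessions of 50-100 consecutive trials
#' before the animal disengages.
#'
#' @param alpha curve location: contrast at the inflection of the internal
#'   detection function. Values above 1 give an effectively flat,
#'   chance-level observer.
#' @param beta curve slope (positive).
#' @param lapse lapse rate \eqn{\lambda} in `[0, 0.1]`: stimulus-independent
#'   errors that cap the upper asymptote at `1 - lapse`.
#' @param bias_side preferred screen panel, 1 (left) or 2 (right).
#' @param bias_strength mixture weight `b` in `[0, 1]`; at `b = 1` every
#'   touch lands on `bias_side`.
#' @param latency_median_correct_s median latency (s) for correct touches.
#' @param latency_sigma log-scale spread of the latency distribution.
#' @param latency_ratio_incorrect multiplier (>= 1) on the median latency
#'   for incorrect touches.
#' @param fatigue_trials trials before the animal disengages, normally in
#'   `[50, 100]`; `NULL` disables fatigue. Values outside 50-100 are
#'   accepted with a warning.
#' @param learning_rate per-session increment to `beta` (>= 0).
#' @param family psychometric curve family, `"logistic"` or `"weibull"`.
#' @param seed integer seed for the observer's random stream.
#' @return an object of class `observer_params`. The guess rate `guess` is
#'   a read-only field fixed at 0.5 by the two-choice task.
#' @seealso [p_correct()], [respond()], [advance_session()],
#'   [observer_preset()]
#' @export
#' @examples
#' obs <- observer_params(alpha = 0.3, beta = 15, lapse = 0.02)
#' p_correct(obs, c(0.1, 0.3, 1.0))
observer_params <- function(alpha = 0.3,
                            beta = 15,
                            lapse = 0.02,
                            bias_side = 1L,
                            bias_strength = 0,
                            latency_median_correct_s = 8.6,
                            latency_sigma = 0.4,
                            latency_ratio_incorrect = 3,
                            fatigue_trials = 100L,
                            learning_rate = 0,
                            family = c("logistic", "weibull"),
                            seed = 1L) {
  family <- match.arg(family)
  if (!is_scalar_number(alpha) || alpha < 0) {
    stop_config("alpha must be a nonnegative number")
  }
  if (!is_scalar_number(beta) || beta <= 0) {
    stop_config("beta must be positive")
  }
  if (!is_scalar_number(lapse) || lapse < 0 || lapse > 0.1) {
    stop_config("lapse must be in [0, 0.1]")
  }
  if (!(bias_side %in% c(1, 2))) stop_config("bias_side must be 1 or 2")
  if (!is_scalar_number(bias_strength) ||
      bias_strength < 0 || bias_strength > 1) {
    stop_config("bias_strength must be in [0, 1]")
  }
  if (!is_scalar_number(latency_median_correct_s) ||
      latency_median_correct_s <= 0) {
    stop_config("latency_median_correct_s must be positive")
  }
  if (!is_scalar_number(latency_sigma) || latency_sigma <= 0) {
    stop_config("latency_sigma must be positive")
  }
  if (!is_scalar_number(latency_ratio_incorrect) ||
      latency_ratio_incorrect < 1) {
    stop_config("latency_ratio_incorrect must be >= 1")
  }
  if (!is.null(fatigue_trials)) {
    if (!is_count(fatigue_trials)) {
      stop_config("fatigue_trials must be a positive integer or NULL")
    }
    if (fatigue_trials < 50 || fatigue_trials > 100) {
      warning("fatigue_trials outside the typical 50-100 trial range",
              call. = FALSE)
    }
    fatigue_trials <- as.integer(fatigue_trials)
  }
  if (!is_scalar_number(learning_rate) || learning_rate < 0) {
    stop_config("learning_rate must be >= 0")
  }
  if (!is_scalar_number(seed) || seed != trunc(seed)) {
    stop_config("seed must be a single integer")
  }
  structure(
    list(alpha = alpha, beta = beta, lapse = lapse, guess = 0.5,
         bias_side = as.integer(bias_side), bias_strength = bias_strength,
         latency_median_correct_s = latency_median_correct_s,
         latency_sigma = latency_sigma,
         latency_ratio_incorrect = latency_ratio_incorrect,
         fatigue_trials = fatigue_trials,
         learning_rate = learning_rate,
         family = family, seed = as.integer(seed)),
    class = "observer_params")
}

# internal detection function F(c) in [0, 1]
psy_curve <- function(contrast, alpha, beta, family) {
  if (family == "weibull") {
    if (alpha <= 0) stop_config("weibull family needs alpha > 0")
    1 - exp(-(contrast / alpha)^beta)
  } else {
    stats::plogis(beta * (contrast - alpha))
  }
}

#' Probability of a correct choice at a given contrast
#'
#' Evaluates the observer's psychometric function (see
#' [observer_params()] for the formula). Monotone nondecreasing in
#' contrast for every valid parameter set; equals 0.5 exactly when
#' `bias_strength = 1` (a pure side-presser is correct half the time under
#' counterbalanced target sides).
#'
#' @param params an [observer_params()].
#' @param contrast contrast fraction(s) in `[0, 1]`; vectorized.
#' @return probability vector, same length as `contrast`.
#' @export
p_correct <- function(params, contrast) {
  stopifnot(inherits(params, "observer_params"))
  if (!is.numeric(contrast) || length(contrast) == 0 ||
      anyNA(contrast) || any(contrast < 0 | contrast > 1)) {
    stop_config("contrast must be in [0, 1]")
  }
  f <- psy_curve(contrast, params$alpha, params$beta, params$family)
  p_unbiased <- params$guess + (1 - params$guess - params$lapse) * f
  (1 - params$bias_strength) * p_unbiased + params$bias_strength * 0.5
}

#' Sample one response (chosen side and latency) from the observer
#'
#' With probability `bias_strength` the observer touches its preferred
#' panel outright; otherwise it touches the target panel with probability
#' `guess + (1 - guess - lapse) * F(contrast)`. The latency is drawn
#' log-normal with median `latency_median_correct_s` for a correct outcome
#' and `latency_median_correct_s * latency_ratio_incorrect` for an
#' incorrect one. Uses (and advances) the current RNG stream; seed it with
#' the observer's stream for reproducibility.
#'
#' @param params an [observer_params()].
#' @param contrast contrast fraction in `[0, 1]`.
#' @param target_side panel showing the striped target, 1 or 2.
#' @return list with `chosen_side` and `latency_s`.
#' @export
respond <- function(params, contrast, target_side) {
  stopifnot(inherits(params, "observer_params"), target_side %in% c(1, 2))
  if (stats::runif(1) < params$bias_strength) {
    chosen <- params$bias_side
  } else {
    f <- psy_curve(contrast, params$alpha, params$beta, params$family)
    p_unbiased <- params$guess + (1 - params$guess - params$lapse) * f
    chosen <- if (stats::runif(1) < p_unbiased) {
      as.integer(target_side)
    } else {
      as.integer(3L - target_side)
    }
  }
  correct <- chosen == target_side
  med <- params$latency_median_correct_s *
    if (correct) 1 else params$latency_ratio_incorrect
  latency <- stats::rlnorm(1, meanlog = log(med), sdlog = params$latency_sigma)
  list(chosen_side = chosen, latency_s = latency)
}

#' Advance the observer by one training session
#'
#' Returns a copy with the detection slope `beta` increased by
#' `learning_rate`, the package's model of training improvement; with
#' `learning_rate = 0` this is the identity.
#'
#' @param params an [observer_params()].
#' @return updated `observer_params`.
#' @export
advance_session <- function(params) {
  stopifnot(inherits(params, "observer_params"))
  params$beta <- params$beta + params$learning_rate
  params
}

#' Shipped observer presets
#'
#' Named parameter sets covering the behavioral archetypes the analysis
#' chain must distinguish: `perfect` (ceiling accuracy), `good_cs`
#' (threshold near 30% contrast), `weak_cs` (threshold near 60%), `biased`
#' (80% side-pressing), `learner` (slope grows across sessions), and
#' `random` (flat, chance-level curve). Stored as JSON under
#' `extdata/observers/`.
#'
#' @param name preset name.
#' @return an [observer_params()].
#' @export
#' @examples
#' observer_preset("good_cs")
observer_preset <- function(name = c("perfect", "good_cs", "weak_cs",
                                     "biased", "learner", "random")) {
  name <- match.arg(name)
  path <- system.file("extdata", "observers", paste0(name, ".json"),
                      package = "swinecs")
  if (!nzchar(path)) stop_config("no shipped preset named '%s'", name)
  observer_from_json(path)
}

#' Read observer parameters from JSON
#' @param path JSON file with fields matching [observer_params()] arguments.
#' @return an [observer_params()].
#' @export
observer_from_json <- function(path) {
  if (!file.exists(path)) stop_config("observer file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$guess <- NULL # read-only, fixed at 0.5
  known <- names(formals(observer_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_config("unknown observer fields: %s", paste(unknown, collapse = ", "))
  }
  do.call(observer_params, raw)
}

#' Write observer parameters to JSON
#' @param params an [observer_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
observer_to_json <- function(params, path) {
  stopifnot(inherits(params, "observer_params"))
  out <- unclass(params)
  out$guess <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.observer_params <- function(x, ...) {
  fat <- if (is.null(x$fatigue_trials)) "none" else x$fatigue_trials
  cat(sprintf(
    paste0("<observer_params> %s curve: alpha=%.3g beta=%.3g lapse=%.3g ",
           "(guess fixed 0.5)\n  bias: side %d, strength %.2f | latency: ",
           "median %.3gs (x%.3g incorrect), sigma %.2f\n  fatigue: %s ",
           "trials | learning: +%.3g beta/session | seed %d\n"),
    x$family, x$alpha, x$beta, x$lapse, x$bias_side, x$bias_strength,
    x$latency_median_correct_s, x$latency_ratio_incorrect, x$latency_sigma,
    fat, x$learning_rate, x$seed))
  invisible(x)
}
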