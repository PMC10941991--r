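# Maximum-likelihood psychometric fit. The curve family is the simulated
# observer's: p(c) = 0.5 + (0.5 - lambda) F(c), guess rate fixed at 0.5 by
# the two-choice design, F logistic (default) or Weibull. The fit is by
# binomial likelihood over the per-contrast (k, n) counts; monotonicity of
# the fitted curve is guaranteed by the parameterization (beta > 0).

fit_bounds <- function(family) {
  if (family == "weibull") {
    list(lower = c(alpha = 1e-3, log_beta = log(0.2), lapse = 0),
         upper = c(alpha = 3, log_beta = log(200), lapse = 0.1))
  } else {
    list(lower = c(alpha = 0, log_beta = log(0.05), lapse = 0),
         upper = c(alpha = 2, log_beta = log(500), lapse = 0.1))
  }
}

psy_prob <- function(contrast, alpha, beta, lapse, family) {
  0.5 + (0.5 - lapse) * psy_curve(contrast, alpha, beta, family)
}

#' Fit a psychometric function to per-contrast performance
#'
#' Maximum-likelihood fit of `p(c) = 0.5 + (0.5 - lambda) F(c; alpha, beta)`
#' to per-contrast correct counts, by bounded quasi-Newton optimization
#' from a coarse grid of starting values (`alpha` over the tested contrast
#' range, `beta` on a log grid, `lambda` in `[0, 0.1]`). Two thresholds are
#' reported:
#'
#' * `threshold_raw` - the contrast at which the fitted percent correct
#'   crosses 50. In a two-choice task the fitted curve's lower asymptote is
#'   the 50% guess rate, so this literal reading is usually undefined and
#'   returned as `NA`.
#' * `threshold_corrected` - the contrast at 75% correct, i.e. the level
#'   recognized (rather than guessed) half the time after correcting for
#'   guessing; this is the headline threshold.
#'
#' A threshold below the smallest tested contrast is flagged
#' `"below measurable range"` (ceiling performance); a threshold above the
#' largest tested contrast, or none, is flagged `"no measurable CS"`.
#'
#' @param points data frame with columns `contrast`, `n`, `k` (e.g. from
#'   [per_contrast_performance()]); at least 3 distinct contrasts.
#' @param family `"logistic"` (default) or `"weibull"`.
#' @return object of class `psychometric_fit` with `alpha_hat`, `beta_hat`,
#'   `lambda_hat`, `threshold_raw`, `threshold_corrected`, `converged`,
#'   `note`, `loglik`, and the input `points`.
#' @export
#' @examples
#' logs <- run_sessions(session_config(seed = 5), observer_preset("good_cs"), 4)
#' fit <- fit_psychometric(per_contrast_performance(logs))
#' fit$threshold_corrected
fit_psychometric <- function(points, family = c("logistic", "weibull")) {
  family <- match.arg(family)
  if (!is.data.frame(points) ||
      !all(c("contrast", "n", "k") %in% names(points))) {
    stop_data("points must have columns contrast, n, k")
  }
  points <- points[points$n >= 1, , drop = FALSE]
  if (length(unique(points$contrast)) < 3) {
    stop_data("need at least 3 distinct contrasts with n >= 1")
  }
  if (any(points$k < 0 | points$k > points$n)) {
    stop_data("counts must satisfy 0 <= k <= n")
  }
  cc <- points$contrast
  kk <- points$k
  nn <- points$n

  nll <- function(par) {
    p <- psy_prob(cc, par[1], exp(par[2]), par[3], family)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(kk * log(p) + (nn - kk) * log(1 - p))
  }

  b <- fit_bounds(family)
  alpha0 <- if (family == "weibull") {
    c(0.1, 0.3, 0.5, 0.8, 1.2)
  } else {
    c(0.1, 0.3, 0.5, 0.8, 1.2, 1.8)
  }
  starts <- expand.grid(alpha = alpha0,
                        log_beta = log(c(2, 8, 25, 80)),
                        lapse = c(0.0, 0.05))
  start_nll <- apply(starts, 1, nll)
  best_starts <- starts[order(start_nll)[seq_len(3)], , drop = FALSE]

  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(best_starts))) {
    opt <- tryCatch(
      stats::optim(as.numeric(best_starts[i, ]), nll, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) {
    return(structure(list(alpha_hat = NA_real_, beta_hat = NA_real_,
                          lambda_hat = NA_real_, family = family,
                          threshold_raw = NA_real_,
                          threshold_corrected = NA_real_,
                          converged = FALSE, note = "optimization failed",
                          loglik = NA_real_, points = points),
                     class = "psychometric_fit"))
  }
  alpha_hat <- best$par[1]
  beta_hat <- exp(best$par[2])
  lambda_hat <- best$par[3]

  thr <- function(pc_target) {
    f_target <- (pc_target / 100 - 0.5) / (0.5 - lambda_hat)
    if (f_target <= 0 || f_target >= 1) return(NA_real_)
    val <- if (family == "weibull") {
      alpha_hat * (-log(1 - f_target))^(1 / beta_hat)
    } else {
      alpha_hat + stats::qlogis(f_target) / beta_hat
    }
    if (!is.finite(val) || val < 0 || val > 1) NA_real_ else val
  }
  t_raw <- thr(50)
  t_corr <- thr(75)

  cmin <- min(cc)
  cmax <- max(cc)
  note <- if (!is.na(t_corr) && t_corr < cmin) {
    "below measurable range"
  } else if (is.na(t_corr) || t_corr > cmax) {
    "no measurable CS"
  } else {
    "ok"
  }

  structure(list(alpha_hat = alpha_hat, beta_hat = beta_hat,
                 lambda_hat = lambda_hat, family = family,
                 threshold_raw = t_raw, threshold_corrected = t_corr,
                 converged = converged, note = note,
                 loglik = -best$value, points = points),
            class = "psychometric_fit")
}

#' Evaluate a fitted psychometric curve
#' @param fit a `psychometric_fit`.
#' @param contrast contrast fraction(s).
#' @return predicted percent correct.
#' @export
predict_percent_correct <- function(fit, contrast) {
  stopifnot(inherits(fit, "psychometric_fit"))
  100 * psy_prob(contrast, fit$alpha_hat, fit$beta_hat, fit$lambda_hat,
                 fit$family)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> %s: alpha=%.3f beta=%.2f lambda=%.3f (guess fixed 0.5)\n",
    x$family, x$alpha_hat, x$beta_hat, x$lambda_hat))
  raw <- if (is.na(x$threshold_raw)) "undefined (curve floored at the 50% guess rate)"
    else sprintf("%.3f", x$threshold_raw)
  corr <- if (is.na(x$threshold_corrected)) "undefined"
    else sprintf("%.3f", x$threshold_corrected)
  cat(sprintf("  threshold (literal 50%% correct): %s\n", raw))
  cat(sprintf("  threshold (guessing-corrected, 75%% correct): %s [%s]\n",
              corr, x$note))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}
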