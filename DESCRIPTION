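Package: swinecs
Title: Touchscreen Contrast-Sensitivity Psychophysics for Large Animals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-alternative
    forced-choice contrast-sensitivity testing of large animals on an
    operant touchscreen. Generates luminance-matched square-wave stripe
    stimuli at calibrated Michelson contrast, runs the trial protocol
    (weight-mat arming, two-panel choice, reward contingency) as a
    deterministic-given-seed state machine driven by a parametric simulated
    observer (logistic or Weibull psychometric curve with guess and lapse
    rates, screen-side bias, outcome-dependent log-normal latencies,
    fatigue, session-over-session learning), and computes the full analysis
    chain: per-contrast performance with exact binomial tests against
    chance, side-bias and bias-accuracy rank correlation, latency
    comparisons, maximum-likelihood psychometric fits with
    guessing-corrected thresholds, and a six-area contrast-sensitivity
    classification of performance points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
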