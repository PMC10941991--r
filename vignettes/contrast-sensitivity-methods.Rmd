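---
title: "Measuring contrast sensitivity with a two-choice touchscreen task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contrast sensitivity with a two-choice touchscreen task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinecs)
```

## The task and what the toolkit models

Contrast sensitivity (CS) — the ability to discern a patterned target from
its background — is measured here with a two-alternative forced-choice
(2AFC) operant task for large animals. A touchscreen is masked into two
panels; one panel shows a black/white striped target at some contrast, the
other a uniform gray control of the same space-averaged luminance. The
animal initiates a trial by stepping off and back onto a weight-sensitive
mat (which guarantees it faces the screen when the trial clock starts),
touches one panel with its snout, and receives a food pellet if and only if
it touched the striped side. Sessions run 50–100 trials before the animal
disengages. Training proceeds in phases: operator-guided trials with the
100%-contrast target, self-run training with the same target (success
criterion: strictly more than 75% correct), and finally the experimental
phase in which ten targets at 10%–100% contrast are each presented ten
times per session in random order.

`swinecs` implements that protocol end to end in software: calibrated
stimulus images, the trial state machine, a parametric simulated animal,
and the analysis chain. Everything is deterministic given a seed, so any
analysis claim in this vignette can be recomputed exactly.

## Stimuli

Contrast is Michelson contrast on linear 8-bit gray levels,
$C = (L_{max} - L_{min}) / (L_{max} + L_{min})$ — the standard metric for
periodic gratings. A target at contrast $C$ with mean gray level $m$ is a
square wave (50% duty cycle, hard edges) alternating between
$\mathrm{round}(m(1 \pm C))$; the control is the uniform field
$\mathrm{round}(m)$. Rounding is half-even, applied identically to both
panels.

Defaults, all configurable because the physical protocol fixes none of
them: mean gray 127.5 (centers the 8-bit range, so 100% contrast renders
as 0/255), 8 stripe pairs per image, vertical stripes, 512×512 px. Gray
levels are assumed proportional to luminance; a real display is gamma-
calibrated externally, which is out of scope here.

Quantization bounds worth knowing: the achieved contrast of a rendered
image is within $1/255$ of the spec at mid-gray, and the stripe/control
means agree to within one gray level. The extreme of that bound is real:
at contrast 0.4 and mean 127.5 both stripe levels land on exact halves and
half-even rounding takes both *down* (178.5→178, 76.5→76), so the stripe
mean is 127 while the control rounds up to 128 — a gap of exactly 1.

```{r stimuli}
img <- make_stripe_image(stimulus_spec(0.4))
c(mean = image_mean(img), contrast = achieved_contrast(img))
```

## The trial engine

The protocol is a small state machine. A trial must be *armed* by a full
mat cycle (step off, then on); touches while disarmed are ignored, as are
contacts below the touchscreen's minimum surface-area threshold (modeled
as a validity flag). An armed trial ends at the first valid touch —
correct iff it lands on the target panel, rewarded iff correct — or at an
optional response timeout, which records an *aborted* trial that is
excluded from every performance denominator. Rewards always equal correct
trials; that conservation is asserted across the test suite.

Schedules counterbalance target sides within each contrast level (5 left /
5 right for 10 repetitions) and then shuffle globally with the schedule
seed. Pure Bernoulli side assignment is available (`iid_sides = TRUE`) but
is not the default: runs of one side under small $n$ would confound the
side-bias analysis. One top-level seed feeds documented sub-streams
(`derive_seed(seed, "schedule")`, `"observer"`, per-session labels) so
either source of randomness can be held fixed.

The engine draws a fresh scheduled trial per arm cycle; whether a physical
system would re-display the same pair after an uncompleted arming is
unknowable from the protocol description, and this choice is the simpler
one.

## The simulated observer

The observer is the package's generative model of an animal:

$$p(c) = (1-b)\,\big[\gamma + (1-\gamma-\lambda)\,F(c;\alpha,\beta)\big] + b\cdot\tfrac12$$

* $F$ — logistic in linear contrast by default (the tested contrast grid
  is linear 10–100%); a Weibull family is provided since the CS literature
  often prefers it.
* $\gamma = 0.5$ — the guess rate, fixed by the two-choice design and
  exposed read-only.
* $\lambda \in [0, 0.1]$ — lapse rate, stimulus-independent errors capping
  the asymptote at $1-\lambda$.
* $b \in [0,1]$ — side bias as a *mixture*: with probability $b$ the
  animal presses its preferred panel regardless of the stimulus. This is
  the simplest mechanism that jointly produces one-sided touching and
  chance-level accuracy — the empirical coupling the bias analysis looks
  for — and is a modeling convenience, not a claim about cognition.
* Latencies are log-normal (right-skewed, like behavioral latencies) with
  median `latency_median_correct_s` (default 8.6 s) for correct responses
  and a `latency_ratio_incorrect`-fold longer median (default 3×) for
  incorrect ones; one spread parameter, since only means and ratios are
  identifiable from session summaries.
* Fatigue: a hard stop after `fatigue_trials` (default 100, the upper end
  of the 50–100 range; presets use 80 where a less cooperative animal is
  being emulated).
* Learning: each session adds `learning_rate` to $\beta$. A slope-only
  learning model means improvement shows at contrasts *above* $\alpha$;
  with $\gamma$ fixed at 0.5 a learner cannot start below ~75% at
  100% contrast unless the target is sub-threshold, in which case a
  steeper slope would lower accuracy. The `learner` preset therefore
  starts near 79% and climbs to ~95% — a qualitative, monotone
  improvement rather than a specific trajectory.

Presets (`observer_preset()`): `perfect`, `good_cs` ($\alpha=0.3$),
`weak_cs` ($\alpha=0.6$), `biased` ($b=0.8$), `learner`, `random`
(flat curve via $\alpha > 1$).

```{r observer}
p_correct(observer_preset("good_cs"), c(0.1, 0.3, 0.6, 1.0))
```

## Analysis chain

All statistics pool non-aborted trials; per-session breakdowns are emitted
for training curves.

* **Per-contrast performance vs chance** — exact two-sided binomial test
  against 0.5 with minimum-likelihood two-sidedness (`stats::binom.test`),
  chosen because per-contrast $n$ is small (10–40); the suite verifies it
  against full outcome enumeration for all $n \le 25$. No multiplicity
  correction is applied across the ten contrasts, matching per-contrast
  significance marking; `p.adjust(..., "holm")` can be applied by the user.
* **Side bias** — percentage of touches on side 1; a minority side below
  25% is flagged as significant bias.
* **Bias–accuracy coupling** — Spearman rank correlation between
  per-session percent correct and bias magnitude $|$side-1 % $- 50|$;
  exact p when untied, asymptotic otherwise; constant inputs raise an
  error rather than returning NA.
* **Latency** — means per outcome, their ratio, and a two-sided
  Mann–Whitney test (latencies are skewed; Welch t is available by flag).
* **Training success** — strictly greater than 75% correct at 100%
  contrast; 75.0% exactly fails.

### Psychometric fit and the threshold

`fit_psychometric()` maximizes the binomial likelihood of
$p(c) = 0.5 + (0.5-\lambda)F(c;\alpha,\beta)$ over bounded
$(\alpha, \log\beta, \lambda)$ with `optim(L-BFGS-B)`, refining the three
best points of a coarse start grid; $\beta > 0$ guarantees a monotone
fitted curve. Non-convergence is flagged, never silently defaulted.

"The contrast recognized 50% of the time" is ambiguous in a 2AFC task,
where 50% *correct* is the guessing floor. Both readings are computed:
`threshold_raw`, the literal 50%-correct crossing, is usually undefined
(the fitted curve never falls to the floor) and reported as `NA` with an
explanatory note; `threshold_corrected`, the 75%-correct crossing
(recognition on half the trials after guessing correction), is the
headline value. Ceiling data are flagged "below measurable range"
(threshold at or under the smallest tested contrast); flat data "no
measurable CS".

```{r fit}
logs <- run_sessions(session_config(seed = 5), observer_preset("good_cs"), 4)
fit_psychometric(per_contrast_performance(logs))
```

## Six-area CS classification

Each (contrast, percent-correct) point falls in exactly one of six areas:
rows are performance bands — ≥75% (good/moderate CS: A1 low-contrast, A2
high-contrast), 50–75% (weak CS: A3/A4), below 50% (random or weak
training: A5/A6) — and columns split at a contrast boundary. The protocol
description fixes the band percentages but not the column boundary; the
default split is 0.5, the midpoint of the tested range, and it is a
configurable `classification_rule()` parameter rather than an asserted
constant. Tie conventions: 75% exactly → upper band; 50% exactly → weak
CS; contrast exactly at the split → low-contrast column.

## What the simulation does and does not establish

The generator reproduces the *structure* of the behavioral data —
contrast-dependent accuracy, side bias coupled to accuracy loss,
outcome-dependent latencies, fatigue, training improvement — under the
study conditions (10 levels × 10 reps/session, 4 sessions pooled, 50–100
trials/session). It does not model inter-trial dependence beyond fatigue,
attention, spatial-frequency-dependent acuity, olfactory or operator cues,
or animal-to-animal idiosyncrasy beyond its parameters. Passing tests
therefore validate the *toolkit* (calibration, protocol logic, estimator
correctness at the study's sample sizes), not any claim about a particular
animal; real deployments should establish per-animal baselines before
treatment comparisons.

Problem sizes used by the verification suite, chosen to mirror the study
design: 40 trials per contrast (4 sessions) per replicate; 50 replicates
for threshold recovery (median $|\hat\alpha - 0.4| < 0.05$); 100
replicates for the significance-pattern contrast of a good-CS observer
(power at contrasts ≥ 60%) against a flat-curve observer (type-I control);
100 seeds for schedule-composition sweeps.

## Numerical and degenerate-input conventions

* Fit probabilities are clamped to $[10^{-9}, 1-10^{-9}]$ inside the
  likelihood; thresholds are reported only inside $[0,1]$.
* Aborted trials: excluded from accuracy, bias, and latency denominators;
  a session that is all aborted raises a data error.
* Undefined statistics (no incorrect trials for the latency ratio, no
  completed 100%-contrast trials for training success, constant vectors
  for the rank correlation) raise classed errors or flagged `NA`s — never
  silent defaults.
* CSV logs: header mandatory, `.` decimal, ISO-8601 dates, lowercase
  `true`/`false`, empty cells for not-applicable fields; reward/outcome
  consistency is validated on read.
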