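---
title: "Models and methods: temporal and spatial context sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temporal and spatial context sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextlearn)
```

contextlearn implements a complete analysis pipeline for two classic
assays of context sensitivity in human perception and learning: a
probabilistic associative learning (PAL) task probing *temporal* context
(how observers track changing cue–outcome contingencies and their
volatility), and a tilt-illusion psychophysics task probing *spatial*
context (how a surrounding grating shifts the perceived orientation of a
central one). Because the pipeline is designed to be validated without
human data, a first-class synthetic-cohort module generates simulated
participants with known ground truth; every guarantee the test suite
makes is a statement about what the pipeline recovers from that known
truth.

## The PAL task generator

On each trial an auditory cue (high or low tone) predicts a visual
outcome (face or house). The contingency `p(face | high tone)` takes one
of three levels — 0.84 (highly predictive), 0.5 (neutral), 0.16 (weakly
predictive) — and changes across contiguous periods of 12, 36 or 72
trials inside three blocks of 168, 120 and 168 trials (456 in total).
Within a period, `p(face | high) = 1 - p(house | high)`, so recoding each
trial as the cue–outcome congruency `u` (1 iff high→face or low→house)
makes `P(u = 1)` equal to the period contingency for both cues; all
learners consume this single binary sequence. Each period crosses both
cues with three image-noise levels in equal numbers, which also balances
the cue marginal within blocks.

Phases: sustained periods of 36 or 72 trials are labelled *stable*;
runs of consecutive 12-trial periods with switching contingencies are
labelled *volatile*. The published design figure is qualitative, so the
exact sequence is configuration (`default_phase_plan()`), not a
constant; the default plan places a long stable run and a volatile run
in each block (288 stable and 168 volatile trials).

Outcomes are drawn independently per trial from the period contingency.
Exact per-period outcome ratios are not enforced — 0.84 × 12 is not an
integer, so exact enforcement is impossible at the period grain; the
balance is instead verified empirically (the Monte-Carlo tests require
the realised `P(u = 1)` in 0.84-periods to match to ±0.02 over 100
schedules).

## Learning models

Four forward filters map `u` to trial-wise beliefs. All are
deterministic and length-preserving.

**Three-level HGF.** The hierarchical Gaussian filter tracks the outcome
(`x1`), the contingency in logit space (`x2`), and the log-volatility of
the contingency (`x3`). Two subject-specific tonic parameters govern the
levels' diffusion: `omega2` (probability learning rate) and `omega3`
(volatility learning rate). Per trial, with previous posterior
(`mu2, sigma2, mu3, sigma3`) and coupling `kappa`:

- prediction: `muhat1 = logistic(mu2)`, prediction error
  `delta1 = u - muhat1`;
- level 2: `v2 = exp(kappa mu3 + omega2)`, `pihat2 = 1/(sigma2 + v2)`,
  `pi2 = pihat2 + muhat1(1 - muhat1)`, update
  `mu2' = mu2 + (1/pi2) delta1`, `sigma2' = 1/pi2`;
- level 3: weight `w2 = v2 pihat2`, volatility prediction error
  `delta2 = (sigma2' + (mu2' - mu2)^2) pihat2 - 1`,
  `pihat3 = 1/(sigma3 + exp(omega3))`,
  `pi3 = pihat3 + (kappa^2/2) w2 (w2 + (2 w2 - 1) delta2)`,
  update `mu3' = mu3 + alpha3 delta2` with
  `alpha3 = (kappa/2) w2 / pi3`, `sigma3' = 1/pi3`.

The *dynamic probability learning rate* reported as `alpha2` is the
precision weight expressed on the outcome-probability scale — the
trial-wise gain of `muhat1`: `alpha2 = muhat1(1 - muhat1)/pi2`. Two
observations force this choice over the raw `mu2`-space gain `1/pi2`:
the raw gain identically equals the posterior variance `sigma2'`
(already a trajectory field) and is not bounded by 1, and its phase
behaviour is dominated by level-1 uncertainty — stable strong-contingency
periods drive predictions to extremes, shrink `muhat1(1 - muhat1)`, and
*raise* `1/pi2`, the opposite of the volatility effect the analysis is
designed to measure. The probability-scale rate is bounded in (0, 1),
rises when the volatility estimate rises, and shows the
volatile-greater-than-stable effect in 20/20 simulated optimal learners
at the canonical parameters (`omega2 = -3`, `omega3 = -6`).

Numerical validity: parameter regions where the level-3 precision `pi3`
turns non-positive (large `omega2`, roughly above -1.4 on this design)
raise a classed `trajectory_invalid` condition carrying the trial index;
the fitting layer scores such points `-Inf`.

**Two-level HGF.** Volatility updates eliminated: `v2 = exp(omega2)`
constant, no level-3 fields. It is the frozen-volatility limit of the
three-level filter (verified against `omega3 = -20` with the level-3
prior pinned).

**Rescorla–Wagner.** `v' = v + alpha_rw (u - v)` with a fixed learning
rate.

**Sutton K1.** A scalar meta-learning rule for the gain:
`delta = u - v`; `b' = b + mu_meta delta h`; `k = min(1, exp(b'))`;
`v' = clip(v + k delta, 1e-6, 1 - 1e-6)`;
`h' = h max(0, 1 - k) + k delta`. The literature names the algorithm but
not a unique variant; this exponentiated-gain scalar form with a unit
cap was chosen for its unconstrained meta-parameter and bounded gain.

Initial states default to `mu2 = 0`, `sigma2 = 1`, `mu3 = 1`,
`sigma3 = 1` and `kappa = 1`, the conventional toolbox settings; all are
config-overridable. Surprise is reported in nats. Regressor timing: the
uncertainty and volatility regressors (`unc1`, `unc2`, `volatility`) are
prediction-time (pre-update) quantities — reaction time on a trial
reflects the beliefs held when the stimulus appears — while surprise uses
the observed outcome. The volatility regressor is `exp(mu3)` rather than
`mu3` (positivity; the alternative is one line of config away since the
trajectory exposes `mu3` too).

## Response model and estimation

Log reaction times (log seconds; the millisecond-to-second conversion is
an additive constant absorbed by the baseline) follow

    log RT(t) ~ Normal(beta0 + beta1 surprise(t) + beta2 unc1(t)
                       + beta3 unc2(t) + beta4 volatility(t), zeta)

with `zeta` the residual variance, parameterised as `log_zeta` for
unconstrained optimisation. Only correct trials with a recorded RT enter
the likelihood. Regressors a learner does not define are absent, not
zero — RW and SK1 contribute surprise and `unc1` only; the two-level HGF
drops the volatility term. Regressors enter unstandardised so the
weights keep their units.

Per subject and model, the joint perceptual + response parameter vector
is estimated by MAP: quasi-Newton (BFGS) ascent of the log joint with
seeded multi-start (default 8 restarts; the first start is the prior
mean, the rest are prior draws scaled by 0.25 — full-width prior draws
frequently start in numerically invalid territory and waste restarts).
Priors are independent Gaussians in the estimation space (identity for
the omegas and betas, log for `zeta` and `mu_meta`, logit for
`alpha_rw`): `omega2 ~ N(-3, 16)`, `omega3 ~ N(-6, 16)`,
`beta ~ N(0, 4)`, `log zeta ~ N(-3, 4)`, `logit alpha_rw ~ N(0, 4)`,
`log mu_meta ~ N(-2, 16)` — weakly informative, config-overridable.

The log model evidence is a Laplace approximation at the MAP:
`log p(y, theta*) + (d/2) log 2 pi - (1/2) log det H`, with `H` the
negative Hessian from central differences (step
`1e-4 max(1, |theta_i|)`). A non-positive-definite `H` is repaired by
eigenvalue clamping and flagged (`hessian_ok = FALSE`). Variational
schemes with richer posterior families exist; MAP + Laplace is the
deliberate scope here, and the test suite checks it exactly on quadratic
log joints where the Gaussian integral is available in closed form.

Random-effects Bayesian model selection treats each subject's generating
model as a draw from population frequencies with a Dirichlet prior
(`alpha0 = 1`) and estimates the posterior by the standard variational
iteration on the log evidences; exceedance probabilities use 10^6 seeded
Dirichlet Monte-Carlo draws (analytic forms exist only for two models).
Subjects with an undefined evidence are excluded listwise with a
message.

## Learning-rate phase analysis

Per subject, `phase_learning_rates()` averages the trial-wise `alpha2`
(and `alpha3` where defined) over stable and volatile trials of the
trajectory implied by the subject's MAP parameters. The 2 (phase) x 2
(group) mixed ANOVA on `alpha2` — the design used for the group
comparison — is computed by the classical split-plot decomposition via
`stats::aov` with an `Error(subject/phase)` stratum, with partial eta
squared per effect from its own error stratum. The full 3 x 3 x 2
condition ANOVA, MANOVAs and Bayes-factor analyses are deliberately not
reimplemented: the pipeline exports tidy condition tables
(`condition_means()`) for any external statistics package, and subjects
with an empty expectedness-by-noise cell are flagged for exclusion the
way incomplete human subjects would be.

## Tilt-illusion pipeline

An observer's orientation discrimination threshold `s` is measured by a
1-up-2-down staircase (0.1° steps, stop after 19 direction reversals,
threshold = mean of the last 13 reversal levels), whose fixed point is
the 70.71%-correct level (the two-down rule balances when
`p^2 = 1/2`). The start difference defaults to 1°, on the order of the
expected threshold: with a fixed 0.1° step, starting several degrees
above threshold leaves the run inside its descent transient for most of
its 19 reversals and biases the last-13 average upward (measured ~79%
correct at a 3° start versus 71.0% at 1°). A degenerate always-correct
observer drives the difference to the floor; a floor bounce counts as a
reversal so the run still terminates, with the threshold clamped at one
step.

The 2IFC illusion block presents seven orientations
`o_i = a_pse + 1.5 s (i - 4)`, centred on the point of perceptual
equality `a_pse` (mean of four adjustment trials) and spaced by 1.5
thresholds, 18 times each in randomised order — 126 trials. (The source
description of this design states "a total of 128 trials" alongside
7 x 18 presentations; 126 is the arithmetically consistent count and is
what the generator emits.)

Responses are fit with the psychometric function
`psi(x) = c + (1 - c - d) / (1 + exp(-b (x - a)))`, guess and lapse
rates fixed at `c = d = 0.02`, by Bernoulli maximum likelihood over
`(a, log b)` from five deterministic starts. `a` is the tilt-illusion
magnitude. Standard errors and the 68% interval for `a` come from a
parametric bootstrap (1000 simulations from the fitted curve, refit from
the fitted parameters); goodness of fit compares the observed deviance
against the saturated binomial model with 1000 Monte-Carlo deviances
simulated from the fit — the deviance is the natural likelihood-ratio
statistic for binomial cells, chosen because the source names only the
simulation count. A fit is excluded when the goodness-of-fit tail
probability falls below 0.05 or the 68% percentile interval for `a` is
wider than the orientation range `o7 - o1` (the only range that phrase
can denote); the percentile rather than SE-based interval is used for
the rule, mirroring how the interval itself is reported.

## The synthetic cohort

`simulate_cohort()` stands in for the human participants. Per subject it
draws ground-truth parameters from Gaussian group distributions,
generates a fresh schedule, runs the three-level HGF, simulates RTs from
the response model, draws error trials, and generates a full tilt
session. Defaults, chosen once as the study conditions the pipeline must
recover:

- `omega2 ~ N(-3, 1)` with a `+0.7` shift of group B's mean (the
  group-difference scenario the analysis is designed to detect);
  `omega3 ~ N(-6, 1)`.
- Response weights `beta0 ~ N(-0.3, 0.2)` (baseline ~740 ms),
  `beta1 ~ N(0.1, 0.03)`, `beta2, beta3 ~ N(0.5, 0.1)`,
  `log zeta ~ N(log 0.04, 0.3)` (residual SD of log RT ~0.2).
- `beta4 ~ N(0.8, 0.2)`: the volatility weight is calibrated so that
  the level-3 signature is identifiable — the module's defining
  requirement is that the full pipeline recovers the generating
  structure, including the three-level model winning model selection.
  At weights much below ~0.5 the volatility regressor contributes under
  1% of log-RT variance and the two extra parameters of the three-level
  model cost more evidence (Occam penalty) than the level-3 signal
  earns, so the generating model becomes unidentifiable by design
  rather than by failure of the fitter.
- Additive log-RT offsets of 0 / 0.03 / 0.06 across image-noise levels
  (the direction of the noise main effect), deliberately absent from
  the fitted model, where they act as realistic unmodelled variance.
- Error probability `logistic(-3.5 + 0.25 noise_index +
  1.0 (1 - p(outcome|cue)))`, giving ~93% overall accuracy and more
  errors on noisy and unexpected trials.
- Tilt observers: illusion magnitude `a ~ N(-1.342, 0.828)` degrees and
  a positive slope around 1.5; PSE adjustment noise 0.3°; log-normal
  discrimination scale (median threshold ~0.9°).

Parameter draws whose HGF trajectory is numerically invalid on the
subject's schedule (~6% of draws, at `omega2` above about -1.4) are
rejected and redrawn deterministically: the generative population is the
valid support of the model. Everything is reproducible from the single
cohort seed; per-subject seeds and ground truth are written to the
manifest, which is the oracle the validation tests compare against.

What the synthetic cohort does *not* emulate: sequential effects beyond
the learner (post-error slowing, fatigue, lapses of attention),
heavy-tailed RT contamination, individual differences in `kappa` or
initial beliefs, and any correlation between a subject's learning
parameters and their tilt observer. Passing tests therefore demonstrate
that the estimator and selection machinery recover structure *when the
generative assumptions hold*, not that those assumptions describe any
particular human dataset.

## Validation scales and numerical choices

The test suite's heavier checks run at deliberately chosen scales:
parameter recovery and model selection on 20 simulated subjects (456
trials each, all four models, seeded multi-start), staircase targeting
on 500 runs, bootstrap-interval coverage on 200 simulated tilt sessions
with 1000 bootstrap refits each, and the phase effect on 20 optimal
learners. These sizes give Monte-Carlo error comfortably inside each
check's tolerance while keeping the default suite in the minutes range.

Tie-breaks and edge cases worth knowing: multi-start keeps the best
finite optimum and reports how many restarts converged; all-identical
responses make a psychometric fit fail fast with an exclusion reason
rather than an optimiser error; an all-stable schedule yields `NA`
volatile means with an explicit attribute rather than silently dropping
the phase; `rfx_bms` normalises each subject's evidences by their row
maximum, making it exactly invariant to per-subject constants.

## Worked example

A miniature end-to-end run (three subjects per group, reduced restarts
and bootstrap for speed; the defaults are larger):

```{r example, eval = FALSE}
res <- run_context_pipeline(
  cohort_spec(n_per_group = 3, seed = 42),
  fit_options = list(n_restarts = 4),
  tilt_options = list(n_boot = 200, n_gof = 0))
res$bms$exceedance_prob
res$phase_anova
res$correlations$tilt_vs_omega2
```

## Known limitations

- MAP + Laplace approximates the evidence; strongly non-Gaussian
  posteriors (weakly identified subjects at very negative `omega2`,
  where the learner barely moves and the RT regressors flatten) can
  place the MAP far from the generating value. The recovery tests
  tolerate a small fraction of such subjects, as the human analysis
  implicitly does.
- The split-plot ANOVA assumes the usual sphericity/normality; with two
  within-levels sphericity is trivial, but the normality of per-phase
  mean learning rates is an approximation.
- Exceedance probabilities are Monte-Carlo estimates; with 10^6 draws
  their error is ~0.001, far below any decision threshold used here.
- The staircase threshold is a biased estimator when the start is far
  from threshold (documented above); the package does not implement
  hybrid or adaptive-step procedures.
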