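# contextlearn

Hierarchical Bayesian learning models and psychophysics for studying
sensitivity to **temporal context** (how people track changing
cue–outcome contingencies and their volatility) and **spatial context**
(how a surrounding grating shifts the perceived orientation of a central
one — the tilt illusion). The package is aimed at computational
cognitive scientists who want a fully tested, simulation-validated
version of this analysis stack: every claim the pipeline makes is
checked against synthetic cohorts with known ground truth.

## What it implements

**Probabilistic associative learning (PAL) task.** A 456-trial schedule
(blocks of 168/120/168) in which `p(face | high tone)` takes levels
0.84 / 0.5 / 0.16 and changes in periods of 12, 36 or 72 trials; long
single-contingency periods form *stable* phases, runs of 12-trial
switches form *volatile* phases. Trials are recoded as the cue–outcome
congruency `u`, balanced over cues and three image-noise levels.

**Four learning models** (trial-wise forward filters on `u`): a
three-level hierarchical Gaussian filter (HGF) with subject-specific
tonic volatilities `omega2` (probability learning) and `omega3`
(volatility learning); a two-level HGF with volatility updates removed;
Rescorla–Wagner; and Sutton K1. The three-level update, per trial:

    muhat1 = logistic(mu2)            delta1 = u - muhat1
    v2     = exp(kappa*mu3 + omega2)  pihat2 = 1/(sigma2 + v2)
    pi2    = pihat2 + muhat1*(1-muhat1)
    mu2'   = mu2 + delta1/pi2         sigma2' = 1/pi2
    w2     = v2*pihat2
    delta2 = (sigma2' + (mu2'-mu2)^2)*pihat2 - 1
    pi3    = 1/(sigma3 + exp(omega3)) + (kappa^2/2)*w2*(w2 + (2*w2-1)*delta2)
    mu3'   = mu3 + (kappa/2)*(w2/pi3)*delta2   sigma3' = 1/pi3

with the dynamic probability learning rate
`alpha2 = muhat1*(1-muhat1)/pi2` and volatility learning rate
`alpha3 = (kappa/2)*w2/pi3`.

**Response model.** `log RT ~ Normal(beta0 + beta1*surprise +
beta2*unc1 + beta3*unc2 + beta4*volatility, zeta)`, fit per subject by
MAP (quasi-Newton, seeded multi-start) with a Laplace approximation of
the log model evidence, followed by random-effects Bayesian model
selection (variational Dirichlet scheme, Monte-Carlo exceedance
probabilities).

**Tilt-illusion pipeline.** 1-up-2-down staircase (0.1° steps, 19
reversals, threshold = mean of last 13 — the 70.71%-correct point),
seven-orientation 2IFC session (`o_i = a_pse + 1.5*s*(i-4)`, 18
repetitions each), logistic psychometric fit
`psi(x) = c + (1-c-d)/(1+exp(-b(x-a)))` with `c = d = 0.02`, parametric
bootstrap SEs, Monte-Carlo goodness of fit, and the standard exclusion
rules.

**Analysis layer.** Condition-mean RT tables (expectedness × noise,
correct trials), stable-vs-volatile learning-rate summaries, a 2×2
mixed (split-plot) ANOVA with partial eta squared, and cross-task
Pearson correlations.

**Synthetic cohorts.** `simulate_cohort()` generates simulated
participants for both tasks with known parameters (including a
configurable between-group shift in `omega2`), serving as the ground
truth for all validation.

## Worked example

```r
library(contextlearn)
res <- run_context_pipeline(
  cohort_spec(n_per_group = 3, seed = 42),
  fit_options = list(n_restarts = 4),
  tilt_options = list(n_boot = 200, n_gof = 0))
print(res)
```

```
Context-sensitivity pipeline: 6 subjects

Random-effects BMS over 4 models, 6 subjects
  model alpha expected_freq exceedance
1  hgf3 2.855        0.2855     0.1868
2  hgf2 5.120        0.5120     0.7766
3    rw 1.020        0.1020     0.0187
4   sk1 1.005        0.1005     0.0179

Phase ANOVA on alpha2:
      effect df1 df2          F          p      peta2
       group   1   4  2.3065734 0.20344574 0.36574114
       phase   1   4 19.1127924 0.01195107 0.82693567
 phase:group   1   4  0.1350189 0.73189991 0.03265255
```

Reading the output: the phase main effect (F(1,4) = 19.1, partial
eta² = 0.83) is the volatility signature — simulated learners update
their contingency beliefs faster in volatile than in stable task phases.
At this toy size (6 subjects, reduced restarts) model selection is
noisy — here the two-level HGF edges ahead; the validation suite runs
the same comparison at 20 subjects with default settings, where the
generating three-level HGF attains exceedance probability above 0.9 and
fitted `omega2` correlates with the generating values at r ≥ 0.6. The
tilt section of the result holds per-subject illusion magnitudes
(population mean −1.34°) with bootstrap SEs and exclusion flags.

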