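---
title: "Measuring the speed of attention with distractor intrusions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the speed of attention with distractor intrusions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrudr)
```

## The measure

In a rapid serial visual presentation (RSVP) stream, a cued target digit is
shown for ~100 ms and is immediately followed by another reportable digit.
When transient attentional engagement is triggered quickly, the target is
encoded; when it is triggered late, the *post-target distractor* benefits
from the attentional amplification instead and gets reported. The
per-participant proportion of such reports — the distractor-intrusion (DI)
rate — is therefore an index of how slowly attention engages. Unlike
reaction-time difference scores, it is a plain proportion over binary trial
outcomes: no subtraction of highly correlated raw scores, no speed-accuracy
trade-off, and consequently very high split-half and test-retest
reliability even in a five-minute task.

`intrudr` implements the full analysis pipeline around this measure: trial
scoring with the task's exclusion rules, reliability estimation including an
iterative down-sampling simulation, a circular time-judgment error pipeline,
frequentist and Bayesian association statistics, and sample-size planners —
all exercised end to end on a calibrated synthetic cohort so that every
stage is testable without access to any particular dataset.

## Scoring rules and their boundary conventions

A DI-trial response is `correct` if it matches the target, an `intrusion` if
it matches the post-target distractor, and `other` (a guess) otherwise; the
three categories always partition the trials. Guess rates above 25% flag a
participant as unable to perform the task (their low intrusion rate is
uninformative); the boundary is read strictly, so exactly 25% is retained.

Attentional-blink (AB) scores come from two-target trials: T1 accuracy,
T2 accuracy at lags 3 and 7, and the AB magnitude `lag7 - lag3` (positive
when the blink is present). T2 accuracy is *not* conditioned on T1-correct
trials by default — the unconditional convention keeps the magnitude a
simple difference of observed proportions — but `ab_scores(condition_on_t1
= TRUE)` provides the conditional variant common in AB work, since the
choice is genuinely open and affects the scale of the measure. A lag with
zero trials yields an undefined (flagged) magnitude rather than 0.

RT preprocessing applies, in this order: a correctness filter (RT analyses
use correct trials only), an absolute window of 150-1000 ms (strict
exclusion outside; the boundary values themselves survive), and a
single-pass per-participant per-condition trim at 3 SDs (strict `>`, mean
and SD computed including the candidate trial). Trial-level filters run
before any participant-level statistic, and the 3-SD passes are not
iterated: a second application of `rt_preprocess()` to its own output
removes nothing. Participant-level outlier flags (3 SDs from the sample
mean, candidate included) are per measure, so a participant excluded from
RT analyses still contributes DI rates.

## The circular time-judgment pipeline

The time-judgment task shows clocks rotating at one rotation per second
(at 60 Hz, the hand steps 6 degrees per frame); the reported hand angle
minus the cued angle, wrapped to the signed interval (-180, 180], is the
time error. We use the half-open wrap with +180 as the boundary
representative so every error is unique and the discard rule below is well
defined at exactly 180. Positive errors are late reports; 1 degree = 1000/360
ms, so the conversion is linear and mean-then-convert equals
convert-then-mean.

Errors at or beyond 160 degrees in magnitude are discarded (an error near
180 is ambiguous between +500 and -500 ms). The discard is *inclusive* of
160. After the discard, a single-pass per-participant 3-SD trim removes
genuinely extreme trials. Because the trim includes the candidate in the
mean and SD, a value can only be trimmed when the participant has enough
trials for the z score to exceed 3 at all (the maximum attainable z in a
sample of n is `(n-1)/sqrt(n)`, so nothing can ever be trimmed from fewer
than 11 trials); this conservatism is intentional and consistent with the
participant-level rule. The mean time error is the arithmetic mean of the
retained signed errors, not the circular mean: after the +/-160 discard the
wrap ambiguity is negligible, and the arithmetic mean is what the M/SD
reporting convention of the field describes.

## Reliability engines

Split-half reliability splits trials by 0-based index parity (even
positions form the first half), scores each half as the intrusion
proportion, correlates the two half scores across participants, and steps
the result up to full length with the Spearman-Brown prophecy formula
`2r/(1+r)`. Cronbach's alpha treats trials aligned by within-participant
rank as items; on binary items it is identical to KR-20, and the test suite
asserts that identity exactly. Zero-variance halves or total scores yield
an explicit undefined signal (`NA` with an attribute), never a silent NaN.

The iterative down-sampling procedure maps average reliability over a grid
of participant counts n and trial counts t: each cell repeatedly samples n
participants and t trials uniformly without replacement (sampled trials
keep their temporal order), computes the corrected split-half reliability
and alpha on the subsample, and averages over iterations with defined
results. Undefined iterations are dropped from the cell mean rather than
imputed — imputation would bias small-n cells — and per-cell valid counts
make this auditable. The default grid runs n = 10..100 and t = 20..80,
both in steps of 2: the trial axis step is given by the procedure's
specification, the participant axis is symmetric by choice (its step is
configurable). One master seed derives an independent, deterministic
stream per cell, so any cell is reproducible on its own.

For measures defined by within-participant contrasts (AB magnitude, RT
effects), `split_half_derived()` scores each half fully — e.g. lag7 - lag3
within the half — before correlating, since correlating raw half scores of
a difference measure would conflate the contrast with its components.

## Association statistics

Correlations are Pearson, on pairwise-complete cases per pair (not listwise
across the whole table), honouring per-measure exclusion flags; partial
correlations use the first-order formula with df = n - 3. Two independent
correlations are compared with the Fisher r-to-z test.

The correlation Bayes factor integrates the exact sampling density of the
Pearson correlation under bivariate normality — the hypergeometric-series
form `(1-rho^2)^((n-1)/2) (1-rho r)^((3-2n)/2) 2F1(1/2, 1/2; n-1/2;
(1+rho r)/2)` — against a beta prior stretched to (-1, 1) with width kappa
(kappa = 1 is uniform, the default of common Bayesian software; 0.5 and 1.5
are reported as robustness). Directional hypotheses truncate and
renormalise the prior to one half-line; for this symmetric prior the
two-sided Bayes factor is exactly the equal-weight average of the two
directional ones, which the tests verify numerically. The likelihood ratio
is integrated on the log scale after locating its peak, so large-n Bayes
factors (e.g. BF10 at r = .3, n = 2000) do not overflow; quadrature uses a
1e-6 relative tolerance and failure raises an explicit error rather than
returning a number.

The t-test Bayes factor is the standard default-prior (JZS) computation: a
Cauchy prior with medium scale `sqrt(2)/2` on the standardised effect,
integrated against the noncentral-t likelihood. Mixed-model or
random-slope Bayes-factor ANOVAs are deliberately out of scope, so
published values from such models are context, not targets, for this
function.

The order correction for counterbalanced task administration subtracts the
between-group mean difference from one group, equalising group means while
leaving within-group variance untouched.

## Power planning

The between-group planner iterates the exact noncentral-t power function
over per-group n and returns the smallest integer achieving the target
power; it depends on the group difference delta and the DI-rate SD sigma
only through d = delta/sigma. With the DI-rate SD of .23 observed in large
online samples, an expected difference of .10 in intrusion rate needs
about 85 participants per group for 80% power two-tailed — which is why
between-group DI designs need care even though the measure is reliable.

The correlation planner uses the Fisher-z approximation
`Phi(sqrt(n-3) atanh(rho) - z_crit)` and records the method name in its
result, because approximations differ across tools: at rho = .40, 80%
power, alpha = .05 one-tailed it returns n = 38. Published planning values
computed with other software (e.g. n = 34 for the same inputs) are not
reproducible without knowing the tail choice and algorithm, so they are
documented but never asserted.

## The synthetic cohort: what it emulates and what it does not

The generator draws one latent attention-speed trait theta per participant
(standard normal; higher = slower attention) and maps it to all task
truths. The intrusion propensity uses an inverse-logit link
`plogis(a + b theta)` with (a, b) solved by Gauss-Hermite moment matching
so the population mean and SD hit their targets (.296/.200 by default);
the link keeps propensities inside (0,1) with a single monotone
parameterisation, and a requested SD at or beyond the `sqrt(m(1-m))` bound
is rejected as an explicit configuration error. Accuracy-type measures
(T1, T2 by lag) use the same link on their own latent variables; bounded
continuous measures (mean time error, mean RT) are affine in theta plus
independent right-skewed noise (a shifted log-normal with skewness ~1.5 —
heavier tails would make finite-sample moments too volatile for stable
calibration). Loadings are solved numerically (nested Gauss-Hermite
quadrature plus root finding) so the *population* product-moment
correlations with the intrusion propensity equal the configured targets:
-.68 with T1 accuracy, +.25 with mean RT, +.40 with mean time error, and 0
with AB magnitude and reading scores. The two T2 lag accuracies share an
encoding-speed factor orthogonal to theta, with the shared loading solved
so the AB-magnitude SD hits .194; reading scores share a reading factor
giving the .53 correlation between word and pseudoword efficiency; age is
orthogonal to theta but loads on RT (+.30), which is what makes the
partial-correlation analysis non-trivial.

Trial generation is then conditionally independent given the profile:
multinomial DI responses over digits 2-9 sampled without within-trial
repetition; AB trials half single-target and half two-target with lags
split at random; time-judgment errors centred on the participant mean with
35-degree trial noise plus a 2% wild-response fraction uniform on the
circle (which exercises the +/-160 filter); RT trials with the design's
condition frequencies (cue present 80%, same-location a quarter of those;
Simon compatible 75%) and condition offsets of +37/-36 ms around the
cue-absent mean and an 81-ms Simon effect. Because propensities are stable
across sessions, test-retest reliability *emerges* from binomial trial
noise alone and matches the attenuation identity
`rho = var(p) / (var(p) + E[p(1-p)]/t)`; at 60 trials per session this
lands near .93, inside the .85-.95 band the tests assert.

Known gaps between the generator and real data, and hence what passing
tests do not show: responses are exchangeable given the profile (no
fatigue, practice, or serial dependence); session-to-session latent drift
is absent, so the emergent retest correlation is an upper-bound scenario;
wild time-judgment responses are homogeneous across participants, so the
+/-160 discard rate (~0.3% at the 2% default) is below the ~2% seen with
real participants whose lapse rates vary; accuracy in the RT tasks is
condition-constant rather than person-varying; and stream count (one vs
two RSVP streams) is a calibration difference, not a mechanism, so the
generator exposes per-study calibration targets instead of modelling it.
Recovered quantities inherit small, known biases from the scoring rules
themselves: the trim and discard stages shade the recovered mean time
error ~5% below the generating 22.41 degrees, and trial-noise attenuation
shrinks observed correlations toward zero — with 60 DI trials the
theoretical shrinkage on the DI-T1 correlation is about 12%, which is why
the parameter-recovery tests use larger trial counts (300 DI / 800 AB /
200 time / 200 RT trials at n = 5000) where attenuation is below .01.

## Numerical choices

Moment matching and loading solutions use 61-node (1-D) and 41x41-node
(2-D) Gauss-Hermite quadrature with `uniroot` at tolerances of 1e-10; the
hypergeometric series is summed to 1e-12 relative tolerance and always
converges on the required domain. Sub-seeds for generator stages and grid
cells are derived deterministically from one master seed and a stage tag,
and stay below 2^31. Degenerate inputs get explicit signals: zero-variance
reliability inputs return flagged `NA`s, empty lags and fully discarded
participants are flagged undefined, planners that exceed their search cap
return a capped result with a warning, and quadrature failures raise
errors. Problem sizes in the test suite (cohorts of 5000 for oracle
agreement at +/-.03 and recovery at +/-.05; 100 x 80 with 100 iterations
for the down-sampling cell) were chosen so that Monte-Carlo error is a
small fraction of each tolerance.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 7)
coh <- simulate_cohort(cfg)
scores <- score_cohort(coh)
s1 <- scores[scores$session == 1, ]

mat <- di_trial_matrix(coh$di_trials, session = 1)
trial_reliability(mat)
retest_reliability(s1, scores[scores$session == 2, ])
downsample_grid(mat, n_values = c(10, 20, 50), t_values = c(20, 50),
                iterations = 100, seed = 7)
cor_pearson(s1$di_rate, s1$t1_acc)
bf_cor(0.40, 38, direction = "positive")
power_curve(seq(0.05, 0.3, 0.05), sigma = 0.23)
```

`run_report()` chains all of the above and writes every artifact (trial
tables, scores, exclusion ledger, reliability JSON, down-sampling grid,
association table with prior-width robustness, power curve, and a text
summary) deterministically from one seed.
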