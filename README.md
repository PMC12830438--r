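# intrudr

Analysis tools for **distractor-intrusion (DI) rates** as an
individual-differences measure of the speed of attention.

## The problem and the measure

In rapid serial visual presentation (RSVP), a cued target appears for
~100 ms inside a stream of distractors. Observers whose transient
attentional engagement is triggered late tend to report the item that
immediately *followed* the target — a distractor intrusion. The
per-participant proportion of such reports, the **DI rate**, indexes the
speed of attention without the two classic weaknesses of reaction-time
measures: it requires no speeded response (so it is immune to
speed–accuracy trade-offs and response-selection variability) and no
difference score (the construction that makes search slopes, cueing and
Simon effects notoriously unreliable). A DI rate measured in a ~5-minute
session (50–60 trials) reaches split-half and test–retest reliabilities
around .90–.95.

The package is aimed at attention researchers who want to score DI tasks,
check how many trials and participants they need, and relate DI rates to
other measures. It implements:

* **Scoring** — response classification (target / post-target / other),
  DI and guess rates, attentional-blink scores
  (`ab_magnitude = t2_lag7 - t2_lag3`), RT preprocessing with the standard
  exclusion cascade, and guess-rate (> 25%) and 3-SD participant flags.
* **Reliability** — split-half with the Spearman–Brown correction
  `r' = 2r/(1+r)`, Cronbach's alpha (= KR-20 on binary trials), test–retest
  correlations, and the iterative down-sampling grid that maps average
  reliability over participant-count × trial-count cells.
* **Time judgment** — signed circular error `(t_p - t_c)` wrapped to
  (−180°, 180°], the inclusive ±160° discard, a per-participant 3-SD trim,
  and degree→ms conversion at one rotation per second.
* **Association** — Pearson and partial correlations, Fisher r-to-z
  comparison of two correlations, Bayes factors for correlations under a
  stretched beta prior (exact sampling density, log-scale quadrature), JZS
  t-test Bayes factors, and the task-order correction.
* **Power planning** — smallest per-group n via the noncentral-t power
  function, and smallest n to detect a correlation via the Fisher-z
  approximation.
* **Synthetic cohorts** — a calibrated latent-trait generator for all four
  task families, so the entire pipeline can be exercised and validated
  end to end without any external data.

## Worked example

```r
library(intrudr)

cfg  <- cohort_config(seed = 7)        # 100 participants, 2 sessions, 60 DI trials each
coh  <- simulate_cohort(cfg)
sc   <- score_cohort(coh)
s1   <- sc[sc$session == 1, ]

mat <- di_trial_matrix(coh$di_trials, session = 1)
trial_reliability(mat)
#> Reliability (100 participants, 60 trials, odd_even split):
#>   r_half = 0.857, Spearman-Brown r' = 0.923, alpha = 0.940

retest_reliability(s1, sc[sc$session == 2, ])
#> r(98) = 0.930, p < .001

downsample_grid(mat, n_values = c(10, 20, 50), t_values = c(20, 50),
                iterations = 100, seed = 7)[, 1:4]
#>    n  t mean_r_sb mean_alpha
#> 1 10 20     0.814      0.795
#> 2 20 20     0.836      0.837
#> 3 50 20     0.837      0.836
#> 4 10 50     0.917      0.909
#> 5 20 50     0.926      0.924
#> 6 50 50     0.931      0.928

cor_pearson(s1$di_rate, s1$t1_acc)
#> r(98) = -0.619, p < .001

bf_cor(0.40, 38, direction = "positive")
#> BF10 = 7.91 (positive, stretched beta width 1.00)

power_curve(seq(0.05, 0.20, 0.05), sigma = 0.23)
#>   delta n_one_tailed n_two_tailed
#> 1  0.05          263          334
#> 2  0.10           67           85
#> 3  0.15           30           38
#> 4  0.20           18           22
```

Reading the output: a 60-trial DI task on this simulated cohort is highly
reliable within a session (r' = .92, alpha = .94) and across sessions
(r = .93); average corrected reliability clears .80 already at 20
participants × 20 trials and exceeds .92 at 50 trials. DI rates correlate
strongly and negatively with T1 accuracy (participants who intrude more
also miss more targets), and an observed correlation of .40 at n = 38
yields a directional Bayes factor of ~7.9 in favour of a positive
association. The power table shows why *between-group* DI comparisons are
expensive: with a between-subject SD of .23, detecting a .10 group
difference at 80% power needs ~85 participants per group two-tailed.

`run_report(cfg, "out/")` chains simulate → score → reliability →
down-sampling → time judgment → associations → power and writes all
artifacts (CSV/JSON plus a text summary) deterministically from one seed.
The methods vignette (`vignettes/distractor-intrusions.Rmd`) documents the
models, calibration, boundary conventions and known limitations.

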