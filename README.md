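# gazeshift

Analysis pipeline for spatial-updating experiments with eye-head gaze
shifts in virtual reality — and a seeded synthetic-data generator with
known ground truth so that every stage can be validated without access to
raw participant recordings.

## What it does

Large gaze shifts combine a saccade with a head rotation, the
vestibulo-ocular reflex holding gaze on target while the head turns. The
classic question is how accurately locations seen *before* such a
movement are localized *after* it. The measurement chain this package
implements:

* **Synthesis** — head-yaw traces (913.68 Hz) with raised-cosine
  velocity profiles obeying the head-movement main sequence
  `peak velocity = 13.22 + 1.27 × amplitude` (deg/s); gaze traces
  (120 Hz) with undershooting primary saccades, VOR stabilization and
  optional secondary saccades; balanced 2AFC trial schedules (7
  comparison offsets from −1.37° to +1.37°, 8 repetitions, 56 trials per
  session); Bernoulli responses from a cumulative-Gaussian observer.
* **Head kinematics** — time-based velocity, 10-sample forward
  moving-average smoothing, 3 deg/s onset/offset criterion, <10°
  amplitude exclusion, OLS main-sequence fit.
* **Eye events** — amplitude-difference saccade detection suited to
  120 Hz (1° onset, 0.1° offset, 30 ms latency) and the target-fixation
  fraction during the head movement.
* **Psychometrics** — maximum-likelihood cumulative-Gaussian fits
  `P(right; x) = Φ((x − PHA)/σ)` giving the point of horizontal
  alignment (accuracy) and just-noticeable difference (precision), with
  the participant-inclusion rule |PHA| ≤ 1.37°.
* **Inference** — within-subject repeated-measures ANOVA with
  Greenhouse–Geisser correction, partial η², observed power,
  Bonferroni-corrected paired t-tests, and per-subject regression of PHA
  on visual velocity gain with one-sample slope tests.

See `vignettes/gaze-shift-analysis.Rmd` for the full model description
and design rationale.

## Worked example

```r
library(gazeshift)

## one synthetic 20-degree head movement, detected back
tr <- generate_head_trace(head_movement_spec(amplitude = 20),
                          duration = 2, onset_time = 0.4, seed = 1)
detect_head_movement(tr)
#> <head_movement_event> valid: 19.92 deg in 878 ms, peak 39.52 deg/s at 0.913 s

## main-sequence recovery through the full detection pipeline
rec <- main_sequence_recovery(n_events = 500, seed = 1)
rec$fit
#> <main_sequence_fit> peak velocity = 13.87 + 1.28 x amplitude (n = 498, residual SD 3.09 deg/s)

## a session of 2AFC trials from a known observer, fitted back
sched <- generate_trial_schedule(trial_schedule_spec(seed = 2))
resp  <- simulate_responses(sched, observer_spec(pha = 0.24, jnd = 0.76),
                            seed = 3)
fit_psychometric(tabulate_responses(resp))
#> <psychometric_fit> PHA = 0.110 deg, JND = 0.668 deg (sigma 0.668, sd convention)
#>   logLik -20.769; included (|PHA| within stimulus range)

## a full simulated velocity-gain experiment
run <- run_experiment(run_config(experiment = 3, n_subjects = 12,
                                 seed = 21, simulate_traces = FALSE))
run$stats$slope_test_unrestricted
#> <effect_result> slopes vs 0: t(11) = 3.153, p = 0.004595
run$stats$anova_pha
#> Repeated-measures ANOVA (Greenhouse-Geisser corrected where needed)
#>   gaze_mode       F(1, 11) = 1.980, p = 0.1871, eta_p^2 = 0.153, power = 0.251
#>   gain            F(1.989, 21.87) = 4.394, p = 0.02505, eta_p^2 = 0.285, power = 0.695 [GG eps = 0.994]
#>   gaze_mode:gain  F(1.635, 17.98) = 2.376, p = 0.1288, eta_p^2 = 0.178, power = 0.381 [GG eps = 0.817]
```

Reading the output: the detected movement loses ~0.1° to the 3 deg/s
threshold at each end (hence 19.92° for a generated 20°); the recovered
main-sequence slope 1.28 matches the generating 1.27, with the intercept
a few tenths high from the same threshold shrinkage; the fitted PHA and
JND recover the generating observer (0.24°, 0.76°) within the sampling
error of one 56-trial session; and the gain experiment — generated with
a true PHA-vs-gain slope of 0.5°/unit for unrestricted gaze shifts —
yields per-subject slopes significantly above zero (one-tailed) and a
significant main effect of gain on the PHA.

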