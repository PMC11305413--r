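---
title: "Analysing eye-head gaze shifts: kinematics, psychometrics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing eye-head gaze shifts: kinematics, psychometrics and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeshift)
```

## The problem this package addresses

When we redirect our line of sight by a large angle, the gaze shift is
composed of a fast saccade of the eyes and a slower rotation of the head,
with the vestibulo-ocular reflex (VOR) counter-rotating the eyes so that
gaze stays put on the new target while the head catches up. Experiments on
spatial updating across such eye-head gaze shifts ask how accurately a
location seen before the movement is localized after it. The standard
design is a two-alternative forced choice (2AFC): a probe is flashed
before the gaze shift, a comparison stimulus is shown after it at one of
seven horizontal offsets (−1.37° to +1.37° in 0.46° steps, eight
repetitions each, 56 trials per session), and the participant reports
whether the comparison appeared left or right of the probe.

`gazeshift` implements the full analysis chain for such experiments —
and, because raw participant data are rarely redistributable, a seeded
synthetic-data generator with known ground truth, so that every stage of
the chain can be validated end to end.

The pipeline has five stages:

1. **synthesis** — head-yaw and gaze traces, balanced trial schedules,
   and 2AFC responses from a cumulative-Gaussian observer;
2. **head kinematics** — velocity-threshold detection of head movements
   and the main-sequence fit;
3. **eye events** — amplitude-difference saccade detection at 120 Hz and
   the target-fixation fraction during the head movement;
4. **psychometrics** — maximum-likelihood cumulative-Gaussian fits giving
   the point of horizontal alignment (PHA) and just-noticeable difference
   (JND);
5. **inference** — within-subject repeated-measures ANOVA with
   Greenhouse–Geisser correction, Bonferroni-corrected post hoc t-tests,
   and per-subject regressions of PHA on visual velocity gain.

## The synthetic observer and trace model

### Head movements

A head movement of amplitude $A$ follows a raised-cosine velocity
profile,

$$ v(t) = \frac{V_p}{2}\left(1 - \cos\frac{2\pi t}{D}\right),
   \qquad 0 \le t \le D, $$

whose integral is exactly $A$ when the duration is $D = 2A/V_p$. The peak
velocity is tied to amplitude by the linear *main sequence*

$$ V_p = 13.22 + 1.27\,A \quad [\mathrm{deg/s}], $$

the empirical amplitude–peak-velocity relationship of natural head
movements, plus optional Gaussian noise. The raised cosine was chosen
because its speed leaves and re-enters zero smoothly, which is exactly
the regime the 3 deg/s onset/offset criterion (below) is designed for;
any smooth unimodal profile with the same displacement identity would
serve equally well.

The orientation of the main-sequence line deserves a note: reading it as
*peak velocity as a function of amplitude* is the internally consistent
choice, because evaluating $13.22 + 1.27 \times 18.83$ (the typical mean
amplitude) gives 37.1 deg/s, matching the typical mean peak velocity of
37.0 deg/s, whereas the converse reading is off by an order of magnitude.
The acceptance suite carries this check.

Head traces are sampled at 913.68 Hz. Measurement noise is modelled as
*band-limited drift* — Gaussian control points every 100 ms, linearly
interpolated, default RMS 0.05° — rather than white noise. This is a
deliberate design choice: white positional noise at ~900 Hz would imply
first-difference velocities with a standard deviation of tens of deg/s,
which no head tracker shows at rest and which would make any
velocity-threshold detector meaningless. Slow drift is the realistic
error mode of tracked headsets.

### Gaze traces

Gaze-in-world traces at 120 Hz compose a trial as: fixation at −10°, a
step-like primary saccade (3-sample ramp) toward the target at +10° that
typically undershoots, a slow corrective glide (per-sample steps below
the 0.1° saccade-offset criterion, i.e. fixational drift) that brings
gaze onto the target by head-movement onset, and then perfect VOR — the
gaze-in-world signal stays constant on the target while the head turns.
In *unrestricted* mode a configurable number of small secondary saccades
of alternating sign is injected during the head movement, which is what
lowers the fixation fraction relative to *sequential* (eyes-first,
then-fixate) gaze shifts. Eye-tracker noise is white with default RMS
0.1°, a plausible figure for consumer HMD eye tracking; both noise levels
are configurable and not empirically calibrated.

### Responses

The 2AFC observer answers "right" with probability

$$ p(x) = \frac{\lambda}{2} + (1-\lambda)\,
   \Phi\!\left(\frac{x - \mathrm{PHA}}{\sigma}\right), $$

where $x$ is the comparison offset, $\lambda$ a lapse rate (default 0),
and $\sigma$ is derived from the generating JND under the same convention
the fitting stage uses, so that recovery studies are self-consistent by
construction.

## Event detection

### Head movements

Velocity is computed by time-based first differences (robust to recorder
jitter), then smoothed with a **forward** moving average of 10 samples —
each smoothed value averages the value at its own index and the nine
following ones. At the tail, where fewer than ten samples remain, the
available samples are averaged; zero-padding would manufacture phantom
slow-downs. The movement peak is the maximum absolute smoothed velocity;
onset is the last sample before the peak with smoothed speed below
3 deg/s, offset the first such sample after it. Events that never exceed
3 deg/s, or whose amplitude is below 10° (half the nominal 20° gaze
shift), are flagged invalid with exactly one exclusion reason — they are
excluded, never errors. When a trace contains several suprathreshold
lobes, the event around the global peak is returned and the extra lobes
are counted in `n_extra_lobes`.

Two numerical consequences are worth knowing. First, the detected
amplitude is slightly *smaller* than the generating amplitude, because
the displacement accumulated while the profile is still below 3 deg/s
(about 0.09° per end for a 20° movement) is not seen between onset and
offset; the property tests bound this shrinkage analytically. Second,
this shrinkage is nearly amplitude-independent, so it biases the fitted
main-sequence intercept upward by a few tenths of a deg/s while leaving
the slope essentially untouched — visible, and accounted for, in the
recovery study below.

### Saccades

At 120 Hz, velocity-based saccade detectors are unreliable, so saccades
are detected from amplitude changes between consecutive samples,
irrespective of elapsed time: onset is the sample immediately preceding
the first consecutive difference of ≥ 1°; offset is the earliest sample
at least 30 ms after onset that deviates < 0.1° from its predecessor.
Scanning resumes after each offset, so events are ordered and
non-overlapping; if the offset criterion is never met the event closes at
the last sample and is flagged truncated. Detection operates on
gaze-in-world (head plus eye-in-head), so VOR counter-rotation does not
masquerade as saccades.

The fixation metric accumulates inter-sample dwell time within the
detected head-movement interval during which gaze is within 1° of the
target (the same window used for fixation control in the trial
procedure) and no saccade is in progress, expressed as a percentage of
the head-movement duration.

## Psychometric fitting

Per participant and condition, "right"-response counts are pooled over
sessions and fitted with $P(\text{right};x)=\Phi((x-\mu)/\sigma)$ by
maximizing the binomial likelihood (BFGS over $(\mu,\log\sigma)$, five
seeded multistarts, relative tolerance $10^{-8}$; ties broken by
likelihood then smaller $\sigma$). Likelihood on counts was preferred to
least squares on proportions because it weights positions by their
binomial information. No lapse term is fitted by default. All-left or
all-right tables are flagged unconverged and report no PHA.

* **PHA** (point of horizontal alignment) is the 50% point $\mu$ — the
  localization *accuracy*.
* **JND** is derived from $\sigma$ — the localization *precision*. The
  convention is deliberately isolated in `compute_jnd()`: the default
  `"sd"` takes JND $= \sigma$ (the 50%→84.1% half-width); `"p75"` takes
  JND $= 0.6745\,\sigma$ (the 50%→75% half-width). Switching convention
  is a single argument, in the generator and fit alike.
* **Inclusion** requires convergence and $|\mathrm{PHA}| \le 1.37°$, the
  presented stimulus range: a participant whose alignment point cannot be
  bracketed by the tested positions yields no interpretable estimate.

## Inference

`rm_anova()` performs the classical univariate within-subject
decomposition (each effect tested against its subject-by-effect
interaction), with sums of squares extracted through `stats::aov` error
strata. The Greenhouse–Geisser $\varepsilon$ is estimated per effect from
the covariance of the orthonormalized within-subject difference scores
(Kronecker contrast construction over the design's factors) and applied
to both degrees of freedom whenever the effect has more than one
numerator df; 2-level factors have $\varepsilon = 1$ identically.
Partial $\eta^2$ is $SS_e/(SS_e+SS_{err})$. Observed power uses the
noncentral $F$ with $\lambda = F \cdot df_1$ at the $\alpha = .05$
critical value — the convention of the mainstream GUI statistics
packages, documented here as approximate.

Post hoc `paired_t()` multiplies the two-tailed p-value by the explicit
family size (Bonferroni), capping at 1. Zero-variance inputs are flagged
degenerate rather than erroring.

For velocity-gain experiments, `fit_gain_slopes()` fits a per-subject OLS
line through the three (gain, PHA) pairs and `slopes_vs_zero()` tests the
slopes against zero. The default is **one-tailed** in the positive
direction: the substantive hypothesis is that larger background gains
drag the alignment point further in the gain direction, and the
one-tailed probability is also the convention consistent with the
reporting style this analysis mirrors. The two-tailed variant is a flag.

## The orchestrated run

`run_experiment(run_config(...))` wires the stages together for three
experiment presets (eye-head 2×2×2; eye-only 2×2; velocity gains 2×3),
fanning one global seed out to per-subject, per-condition, per-trial
substreams through a Lehmer-mixed hash, so that neighbouring substreams
are statistically unrelated and the whole run is bit-identical under a
fixed config. Trial exclusions are counted and reported in the manifest.
Generating observers draw per-subject baselines (PHA ~ N(0, 0.15°), JND
log-normal around 0.8°) with small fixed condition effects — values
chosen once as representative of localization experiments of this kind —
and, for the gain preset, a PHA that is linear in gain (default slope
0.5°/unit for unrestricted, 0 for sequential gaze shifts).

## What the tests do and do not show

Every detector is checked for exact agreement with an independent
brute-force transcription of its rules on randomized traces; the
psychometric MLE is checked against a dense grid search and for
reflection/translation equivariance; the ANOVA is checked against a
longhand inclusion-exclusion sums-of-squares oracle to $10^{-10}$,
against $F = t^2$ for 2-level factors, and for null calibration at
$\alpha = .05$ over 1000 replicates. Recovery studies (problem sizes: 500
movements for the main sequence; 200 replicates × 448 trials for the
psychometric bias bounds; 12–25 simulated subjects for slope recovery)
confirm the pipeline recovers its generating parameters within simulation
error.

What passing these tests does **not** show: the generator's traces are
idealized (single movement per trial, perfect VOR, band-limited noise, no
blinks, no tracking loss, no torsion), so real recordings will stress the
detectors in ways synthetic data cannot. The fixation-duration and
amplitude summaries inherit whatever biases the detectors have on real
signals; the exclusion rate observed on synthetic data says nothing about
empirical exclusion rates. The inferential stage assumes balanced,
complete within-subject tables — unbalanced designs are out of scope.

## Known limitations

* Yaw only; no pitch/roll, no translation, no binocular geometry.
* No optokinetic-nystagmus modelling; the background grating enters only
  through the velocity-gain displacement rule.
* No Bayesian psychometric estimation or adaptive staircases.
* The saccade detector is specified for ~120 Hz data; at much higher
  rates the consecutive-sample 1° criterion becomes conservative.
* Observed power is the noncentral-F approximation above, not a
  simulation-based power estimate.
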