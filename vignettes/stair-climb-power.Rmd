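---
title: "Estimating stair climb power from a lumbar-worn inertial sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stair climb power from a lumbar-worn inertial sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairclimbr)
```

## The measurement problem

The Stair Climb Power Test (SCPT) is a standard clinical assessment of
lower-limb muscular function: a participant climbs a short staircase
(four steps in the protocol this package targets) as fast as safely
possible while a clinician times the climb with a stopwatch. Stair climb
power (SCP) is the mechanical power delivered lifting body mass through
the staircase height,

$$P_{\mathrm{SC}} = \frac{m\,g\,h}{t},$$

with mass $m$ (kg), $g = 9.81\ \mathrm{m/s^2}$, staircase height $h$ (m,
about 0.6 m for four 0.154 m steps) and stopwatch time $t$ (s). Stopwatch
timing is subject to human error and confined to the clinic. This package
estimates the same quantity from a six-axis inertial measurement unit
(IMU) worn on the lower back near L5, where the sensor approximately
tracks centre-of-mass motion. Axis convention throughout: x = vertical
(gravity-inclusive), y = medial-lateral, z = anterior–posterior.

Three computational problems make up the pipeline:

1. **When is the wearer on the stairs?** Windowed signal features feed
   binary classifiers for stair walking vs. level gait and for stair
   ascent vs. descent.
2. **When does each foot strike a step?** A wavelet-based detector finds
   initial contacts in the vertical acceleration of an ascent event.
3. **How much power?** Detected inter-contact intervals are converted to
   power, and the sensor estimate is validated against the stopwatch
   value with agreement statistics.

## The sensor power model

With per-step height $h_4$ and detected contact times
$t_1 < t_2 < t_3 < t_4$, the climb time visible to the sensor misses the
interval between the "go" command and the first contact. During that
interval essentially no vertical work is done, but the stopwatch includes
it, so the sensor formula imputes it as $t_0$, the mean detected step
interval:

$$P_{\mathrm{SC}} =
\frac{m\,g\,h_4 \cdot (\text{steps detected})}
     {t_0 + (t_2 - t_1) + (t_3 - t_2) + (t_4 - t_3)},
\qquad t_0 = \operatorname{mean}_j (t_{j+1} - t_j).$$

Because the denominator telescopes, this expression reduces exactly to

$$P_{\mathrm{SC}} = \frac{m\,g\,h_4}{\operatorname{mean}(\text{valid intervals})},$$

which is the form `stairpy_scp()` computes. The reduction is what lets
the estimator extend gracefully to partial detections: when a contact is
missed, the interval spanning the gap exceeds the misdetection threshold
and is simply excluded from the mean (the equivalence on complete,
all-valid trials is asserted to $10^{-12}$ in the test suite). An
optional additive calibration offset (`apply_calibration()`) is provided
but defaults to 0 W: the $t_0$ imputation is already the principled
correction for the "go"-to-first-step period, and we treat the
uncalibrated estimate as primary.

## Initial-contact detection

`detect_initial_contacts()` applies, in order: (1) a wavelet-style
detrend that subtracts the coarse Gaussian-smooth component of the
vertical acceleration (removing gravity and posture drift); (2) a
zero-phase low-pass Butterworth filter; (3) cumulative
composite-trapezoid integration, turning acceleration into a
velocity-like signal in which each step is a rapid rise; (4) a continuous
first-derivative-of-Gaussian wavelet transform, which responds maximally
to those rises; (5) peak detection with prominence and separation
constraints. This is the lumbar-CWT family of gait event detectors,
adapted to the short, vigorous four-step burst of an SCPT trial.

Every stage is zero-phase or symmetric, so detected times are not biased
by filter group delay. Two behaviours deal with realities of field data:
peak polarity is resolved at run time (the vertical axis sign depends on
how the device is worn) by keeping the polarity with the larger total
prominence, and if more than the expected number of peaks survive, the
most prominent `expected_steps` are kept — spurious early peaks from the
"go" weight shift are common.

The tunable constants, all in `detector_config()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `lowpass_cutoff` | 5 | Hz | stair-stepping content at natural pace is < 5 Hz |
| `lowpass_order` | 4 | — | steep enough rolloff without ringing (applied zero-phase) |
| `detrend_scale_s` | 1.5 | s | slower than any step cycle, so only posture/gravity is removed |
| `cwt_scale_s` | 0.35 | s | pseudo-period of peak wavelet response, matched to contact rise time |
| `min_peak_separation` | 0.3 | s | faster alternation than ~0.3 s is not physiological on stairs |
| `peak_prominence_frac` | 0.5 | of sd | scale-free threshold; makes detection amplitude-invariant |
| `max_interval_s` | 1.2 | s | intervals above 1.2 s correspond to missed contacts on a 4-step stair |

Wavelet scales are expressed as pseudo-periods: the Gaussian-derivative
kernel's standard deviation is `scale_s / (2 * pi)`, placing the peak of
its frequency response at `1 / scale_s` Hz. The misdetection threshold is
boundary-inclusive (an interval of exactly 1.2 s is valid).

Degenerate inputs are refused explicitly: non-finite samples, rates below
50 Hz, events shorter than 1 s, and signals that are flat after
detrending (e.g. pure gravity) raise errors naming the failing stage.

## Resampling

Recordings arrive at 128 Hz (or any rate at least 50 Hz) and are
downsampled to 50 Hz before windowing so results generalise to
lower-rate devices. `resample_recording()` is anti-aliased and
zero-phase: each channel is (a) extended at both ends by Burg
linear-prediction extrapolation — band-limited signals obey a low-order
autoregression, so this avoids the edge kinks of mirror padding — (b)
low-pass filtered with an order-8 Butterworth at 90% of the target
Nyquist frequency, run forward and backward with steady-state initial
conditions so constants pass exactly, and (c) interpolated onto the
target grid with a Kaiser-windowed sinc kernel (half-width 48 samples,
beta 20) whose weights are renormalised to preserve constants. The
implementation keeps a constant channel to within $10^{-9}$ and makes
128→100→50 Hz agree with direct 128→50 Hz resampling to below
$10^{-6}$ RMS on band-limited input.

## Windowing and features

Recordings sliced by annotated events are cut into 1.5 s windows with
50% overlap; at 50 Hz that is a 75-sample window. Half of 75 is
fractional, so the hop is `floor(W/2) = 37` samples, keeping the realised
overlap at or above 50%. Windows never straddle an event boundary
(windowing is applied per sliced event), so each window carries exactly
one activity label.

Each window yields a fixed, named feature vector: per sensor and axis a
23-item set (moments, order statistics, amplitude-histogram entropy,
spectral entropy, lag-1 autocorrelation, dominant frequency, non-DC FFT
energy, zero crossings), plus three cross-axis Pearson correlations per
sensor — 72 features per sensor — and, for the accelerometer only,
per-axis signal range and a vertical-axis step-band wavelet energy
(Gaussian-derivative response at 0.5 s pseudo-period, i.e. the ~2 Hz
stepping band), for 76 accelerometer features and 148 in total. The
gyroscope-free configuration (76 features) supports accelerometer-only
deployments, where battery life favours a single sensor.

Conventions fixed where definitions are genuinely open: histogram entropy
uses 10 equal-width bins over `[min, max]` with the maximum included in
the last bin; autocorrelation is at lag 1; all zero-variance cases
(entropy, autocorrelation, correlations, dominant frequency) are defined
as 0. Windows are *not* re-detrended before feature extraction: the
vertical accelerometer mean carries gravity/orientation content that is
genuinely discriminative for stair walking, and removing it would
discard that signal.

## Classifier protocol

Two binary tasks: stair walking (ascent + descent) vs. gait, and ascent
vs. descent. The protocol is: balance classes 1:1 by subsampling
negatives within each subject × visit stratum (`balance_classes()`);
drop features with absolute pairwise correlation above 0.90 by a greedy
scan in canonical order (`drop_correlated_features()`); select features
by recursive elimination, one per iteration, ranked by random-forest
impurity importance and scored by subject-grouped 5-fold accuracy
(`select_features_rfecv()`); then evaluate k-nearest-neighbours, random
forest, ridge logistic regression and a soft (probability-averaging)
voting ensemble under subject-grouped 10-fold cross-validation with a
grid search on the training side of each fold (`train_and_evaluate()`).

Design choices worth stating:

* **Grouping.** Fold assignment is by subject, and the empty
  intersection of train and test subjects is asserted inside every fold.
  Overlapping windows from one subject are highly correlated; pooled CV
  would leak and overstate accuracy.
* **"10-fold CV" and "80/20 split".** Both protocols appear in clinical
  ML practice; grouped 10-fold (≈90/10 by subject, grid search inside
  each fold) is the primary mode, and a one-shot 80/20 subject holdout is
  available as `mode = "holdout"`.
* **Grids.** knn $k \in \{3,5,7,11\}$; forest trees $\in \{100, 300\}$
  with node cap $\in \{\infty, 1024\}$; logistic inverse regularisation
  $C \in \{0.1, 1, 10\}$ mapped to a ridge penalty
  $\lambda = 1/(Cn)$ (glmnet). Features are z-scored on the training
  side of each fold only — required by knn and logistic regression,
  harmless for trees.
* **Metrics.** Accuracy, sensitivity on the positive class (stair
  walking, or ascent) and specificity, reported as mean (sd) across
  folds. Random-forest impurity importances are averaged across folds and
  normalised to sum to one (`compute_feature_importances()`).

## Agreement statistics

Validation of sensor power against the stopwatch value uses per-subject
paired means: Pearson correlation; ICC(2,1) — two-way random effects,
absolute agreement, single measurement — computed from the two-way ANOVA
mean squares, with the F-distribution (McGraw–Wong) confidence interval,
chosen because only the ICC form, not the CI method, is conventionally
pinned down; Bland–Altman bias and 95% limits of agreement with
normal-theory confidence intervals, differences taken Standard minus
sensor; and Welch unequal-variance t-tests (fractional
Welch–Satterthwaite df) for age- and sex-group comparisons. All four are
cross-checked in the test suite against independent oracles: the raw
Pearson sum formula, `aov`-derived mean squares, hand formulas for the
limits, and the textbook Welch statistic.

## The synthetic trial generator

No public recording of the original protocol exists, so
`simulate_scpt_trial()` / `simulate_labeled_dataset()` generate six-axis
lumbar signals with known ground truth. A trial draws inter-contact
intervals uniformly from 0.4–1.0 s (natural-pace four-step climbs).
Each contact contributes a Gaussian net-impulse transient plus a
Gaussian-enveloped 8 Hz ring to the gravity-inclusive vertical axis —
a foot strike transfers net vertical momentum and excites a short
heel-strike vibration. A step-cycle oscillation *phase-locked to the
contacts* (peaking at each strike, as trunk vertical acceleration does)
spans the stepping burst with smooth onset and offset; a free-running
sinusoid would be unphysical and, tellingly, defeats wavelet detection
in a way real signals do not. Anterior–posterior, medial-lateral and
gyroscope channels carry locomotor oscillations with a random
per-recording phase; stair ascent and descent differ in impact sharpness
and in the sign of a trunk-pitch gyroscope bias. Noise is low-pass
filtered (coloured) white noise, 0.3 m/s² on the vertical channel by
default.

Subject-level random effects (preferred step interval, amplitude
multiplier, gait frequency) make subjects statistically distinct, so
grouped and pooled cross-validation differ measurably and fold-leakage
bugs are detectable. A `class_contrast` dial scales every
class-distinguishing component; at 0 all three activities reduce to the
same gait process, a built-in null under which classifier accuracy sits
at chance — the test suite checks both ends.

What the generator does *not* emulate: handrail use, turning, fatigue
drift, free-living background activity, sensor misorientation beyond a
sign flip, and the full biomechanics of descent power (descent power is
deliberately out of scope). Passing tests therefore demonstrate that the
algorithms are correct and well-calibrated under the stated signal
model, not that in-clinic accuracy figures transfer to any particular
cohort.

## Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale problem
sizes chosen as the smallest that exercise every code path with stable
statistics: 200 simulated trials for step-time/power recovery, 10
subjects × 2 trials (≈ 300 balanced windows) for the classifier
protocol, 500 replicates for the ICC noise-collapse check and n = 500
subjects for ICC parameter recovery. Every stochastic stage takes a
seed; seeded runs are bitwise reproducible, and seeded generator calls
restore the caller's RNG state on exit.

## Known limitations

* The detector constants are engineering defaults, exposed in
  `detector_config()`; the upstream method family does not pin them
  down, and devices with very different mounting may need retuning.
* The step-band wavelet energy is a stand-in with the same intent as the
  wavelet measures in the stair-recognition literature; the exact
  published measures are not reproduced here.
* ICC confidence intervals assume the two-way model's normality; with
  very small n they are approximate.
* The calibration hook is a plain additive offset. Whether a further
  correction beyond the $t_0$ imputation is warranted is left to the
  user; we default to none.
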