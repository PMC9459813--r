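# stairclimbr

Stair climb power (SCP) is a clinical measure of lower-limb muscular
function, assessed with the Stair Climb Power Test: a participant climbs a
short staircase (four steps here) as fast as safely possible and a
clinician times the climb. The stopwatch power is

    P = m · g · h / t        [W]

with body mass *m* (kg), *g* = 9.81 m/s², staircase height *h* (m) and
stopwatch time *t* (s). Stopwatch timing is error-prone and clinic-bound.
`stairclimbr` estimates the same quantity from a six-axis inertial sensor
worn on the lower back: a wavelet-based detector finds the initial contact
of each step in the vertical acceleration, and power is computed from the
detected inter-step intervals as

    P = m · g · h4 / mean(valid intervals)

where *h4* is the per-step height (0.154 m by default) and an interval is
valid when it is at most 1.2 s (longer intervals indicate a missed
contact). This is algebraically identical to the explicit formulation in
which the unobserved time from "go" to the first step is imputed as the
mean step interval (t0).

The package is aimed at digital-biomarker and movement-science researchers
working with lumbar IMU data. It provides the full processing chain:

* **IMU I/O** — delimited-text recordings (`t, ax, ay, az, gx, gy, gz`),
  event annotations, anti-aliased zero-phase resampling, event slicing;
* **Segmentation & features** — 1.5 s windows with 50% overlap; a fixed
  148-item feature vocabulary (76 accelerometer + 72 gyroscope);
* **Step detection** — detrend → zero-phase Butterworth → trapezoid
  integration → Gaussian-derivative wavelet → prominence peak picking,
  with the 1.2 s misdetection filter;
* **Power** — stopwatch and sensor formulas plus an optional calibration
  offset;
* **Classifiers** — stair-vs-gait and ascent-vs-descent under a
  subject-grouped 10-fold cross-validation protocol (knn, random forest,
  ridge logistic regression, soft voting ensemble) with class balancing,
  a correlation filter and recursive feature elimination;
* **Agreement statistics** — Pearson, ICC(2,1) with F-based confidence
  intervals, Bland–Altman limits of agreement, Welch t-tests;
* **A synthetic trial generator** with known ground truth, so every stage
  is testable without clinical data.

## Worked example

Simulate one four-step trial for a 70 kg subject, downsample to 50 Hz,
detect contacts and estimate power:

```r
library(stairclimbr)

trial <- simulate_scpt_trial(synthetic_config(seed = 7), mass = 70)
round(trial$truth_contacts, 3)   # 1.000 1.993 2.632 3.101 (ground truth, s)
trial$true_scp                   # 150.97 W

rec <- resample_recording(trial$recording, 50)
det <- detect_initial_contacts(rec$accel[, "x"], rec$fs)
det
#> <step_detection> 4 contacts (expected 4) @ 50 Hz
#>   contacts (s): 1.000, 2.000, 2.620, 3.120
#>   intervals (s): 1.000, 0.620, 0.500

stairpy_scp(70, det)
#> <scp_result> 149.65 W (stairpy)
#>   mass 70.0 kg, step height 0.154 m, t0 0.707 s, 3 valid interval(s)
```

All four contacts are recovered within one or two samples of the truth and
the power estimate (149.65 W) lands within 1% of the true 150.97 W. The
printed `t0` is the mean of the valid intervals — the imputed time between
"go" and the first step. `agreement_report(standard, sensor)` then
quantifies agreement across a cohort (Pearson r, ICC(2,1), Bland–Altman
bias and limits, group t-tests), and `train_and_evaluate()` runs the
activity-classification protocol; see the vignette
(`vignettes/stair-climb-power.Rmd`) for the full methods account.

A thin command-line wrapper over the same functions ships with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "stairclimbr.R", package = "stairclimbr"))') \
    simulate --activity scpt --n 1 --seed 7 --out demo/
```

with commands `simulate`, `segment`, `featurize`, `detect-steps`, `scp`,
`train` and `agree`.

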