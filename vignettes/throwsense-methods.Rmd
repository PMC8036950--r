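---
title: "From wrist-worn IMU signals to throw workload: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist-worn IMU signals to throw workload: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(throwsense)
```

## The problem

Handball exposes the throwing shoulder to hundreds of high-velocity overhead
throws per week, and throwing workload — how many throws, of which kind, at
what intensity — is a central quantity for injury-prevention monitoring.
Counting and rating throws by hand is impractical, so this package
implements an automated pipeline: a wrist-worn 9-DoF inertial measurement
unit (IMU) records low-g (±16 g) and high-g (±200 g) accelerometer and
gyroscope (±2000 °/s) signals; the pipeline detects each throw, summarises
it as a fixed feature vector, and feeds machine-learning models that
classify the approach type (standing, running, jumping) and wind-up style
(circular, whip-like) and predict peak ball velocity, the intensity proxy a
radar gun would measure.

Because raw athlete recordings are privacy-restricted, the package ships a
seeded simulator that generates multi-rate IMU sessions with ground-truth
events, labels, and velocities. Every stage of the pipeline is exercised and
tested against that simulator.

## Pipeline stages

### Resampling

The sensors ship at nominal rates of 1125 Hz (low-g accelerometer,
gyroscope) and 1600 Hz (high-g accelerometer) but fluctuate around them.
`resample_linear()` places each channel on an exact uniform grid — 1150 Hz
for the low-g accelerometer and gyroscope, 1600 Hz for the high-g
accelerometer — by linear interpolation between the bracketing raw samples.
Three choices were genuinely open and are fixed as follows:

* the grid is anchored at the first input timestamp (`t0 = t[1]`), which is
  deterministic and phase-unambiguous;
* the grid never extends beyond the last input sample (no extrapolation);
* non-finite raw rows are dropped (and counted) before interpolation rather
  than imputed, so gaps are bridged by the interpolant explicitly.

Resampling a signal already on the target grid reproduces it to floating
precision, and interpolated values can never leave the range of the input —
both are tested properties.

### Throw detection

A throw is the only event in a handball session that drives the wrist's
gyroscope y-axis past 1500 °/s, so detection thresholds that axis:
contiguous runs of samples at or above `threshold_dps` (default 1500 °/s)
become candidate events located at the run maximum, and candidates closer
together than `min_separation_s` (default 1 s — distinct throws cannot recur
faster) are merged keeping the larger peak. The signed y-axis is
thresholded by default; `use_abs = TRUE` switches to the absolute value for
mounting conventions that flip the rotation sign.

Windows of 2, 3, 4, and 6 s are cut centered on each event. Each sensor is
located by *time*, not by shared sample index, so the multi-rate streams
stay aligned; a 2 s gyro window at 1150 Hz is exactly 2300 samples. Windows
that would cross the recording boundary are discarded rather than padded,
because padding distorts both spectral and moment features.

### The 201-feature inventory

Each throw window is summarised by a fixed, versioned catalogue of 201
features: 12 channels (three sensors × {x, y, z, vector magnitude}) × 16
per-channel statistics, plus the 3 between-axis Pearson correlations of each
sensor (12 × 16 + 9 = 201). The 16 statistics are mean, sum, sd, variance,
coefficient of variation, min, max, peak-to-peak amplitude, interquartile
range, skewness, kurtosis, power, RMS, lag-1 autocorrelation, dominant
frequency, and spectral entropy. Names follow
`<acc|gyr>_<x|y|z|vm>_<stat>`, with suffix `_h` for the high-g
accelerometer.

Numerical conventions, chosen for determinism on degenerate windows:

* skewness and kurtosis are the Fisher moment definitions (kurtosis as
  excess), without small-sample bias correction; both return 0 for a
  (numerically) constant signal;
* `cv = sd / |mean|`, returning 0 when `|mean| < 1e-12`, which avoids
  infinities on zero-mean gyro channels;
* `power` is the mean of squares; `rms` its square root;
* `autocorr_lag1` is the Pearson correlation of `v[1:(n-1)]` with `v[2:n]`,
  0 under (near-)zero variance;
* `dominant_frequency` is the argmax of the periodogram of the mean-removed
  signal, excluding the zero bin, with ties broken toward the lower
  frequency; `spectral_entropy` is the Shannon entropy of the normalised
  periodogram divided by `log(#bins)`, so it lies in [0, 1];
* between-axis correlations use the measured axes only — the derived vector
  magnitude is excluded — and return 0 for a zero-variance axis.

Every statistic is verified against an independent brute-force
implementation (explicit sums and an O(n²) DFT) to 1e-9 relative, and
against closed forms for pure tones.

The high-g and low-g *range sets* both contain the 67 gyroscope features and
add the 67 features of their accelerometer, 134 columns each. Comparing
models fit on the two sets isolates what the wider measurement range is
worth.

### Modelling

Four families run through one identical skeleton per leave-one-subject-out
(LOSO) fold — correlation-prune, standardize, tune, fit, predict:

* random forest (`randomForest`),
* linear-kernel SVM and polynomial-kernel SVM (`e1071`),
* gradient boosting machine (`xgboost`).

Correlation pruning greedily removes features until no retained pair has
|r| > 0.95: at each step the worst pair is found and the member with the
larger mean absolute correlation to the remaining features is dropped (ties
drop the later catalogue column). Standardization subtracts the training
mean and divides by the training sd (zero-variance columns get scale 1 and
are flagged). Hyperparameters are selected by seeded 10-fold
cross-validation (stratified by class for classification) over small
standard grids; a single-point grid short-circuits the search.

Both preprocessing steps run *inside* each LOSO training fold by default.
Fitting them on the pooled data before splitting would leak the held-out
subject's distribution into the transform; `global_preprocess = TRUE`
reproduces that literal reading for comparison. The leakage guarantee is
tested directly: corrupting a held-out subject's labels cannot change the
predictions made for that subject.

Classification is scored one-vs-rest per class with sensitivity,
specificity, balanced accuracy (their mean), and F1; regression with MAE,
RMSE, and MAPE. Permutation importance measures the mean drop in score over
seeded column permutations, clipped at zero and scaled so the best feature
reads 100. The alternative reading of feature importance — refitting without
each feature — is ambiguous in origin and two orders of magnitude more
expensive; column permutation is the standard desk-scale choice.

### Model and range comparison

Per-subject LOSO metrics (macro F1 for classification, MAE for velocity)
form a complete two-way within-subject design: 4 model families × 2
measurement ranges per subject. `rm_anova_two_way()` computes the standard
balanced within-subject decomposition, with each effect tested against its
subject-by-effect interaction. Sphericity is handled with the
Greenhouse–Geisser correction; epsilon is the Box estimate from the sample
covariance of the effect's orthonormal contrast scores (exactly 1 for
two-level factors, which admit no sphericity violation). The implementation
is verified to 1e-9 against a hand-computed four-subject example, against
base R's `aov()` error decomposition, and against `car::Anova()`'s
multivariate-model epsilon and corrected p-values; its type-I error under
an iid null stays at or below nominal in simulation, as expected from a
conservative correction.

Range contrasts are paired within-subject differences (high-g minus low-g)
within each stratum, Holm-adjusted across strata. On a balanced design
these equal the estimated marginal-means contrasts of the fitted ANOVA, so
no separate marginal-model machinery is needed. The family-wise alpha is
fixed at 0.05.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the study conditions the pipeline
assumes: 17 subjects, 6 conditions (3 approaches × 2 wind-ups), 7–10 throws
per condition per subject, throws 8 s apart, and per-condition velocity
Normals (standing 20.7 ± 2.6 / 20.1 ± 2.5, running 22.0 ± 2.4 / 21.2 ± 2.4,
jumping 21.4 ± 2.5 / 21.0 ± 2.4 m/s for circle/whip), truncated to
[15, 30] m/s. Timestamps jitter by ±10 % of a sample period around the
nominal 1125/1600/1125 Hz rates, so resampling is genuinely exercised.

Each throw is built from raised-cosine pulses — smooth, band-limited, and
analytically integrable for oracle checks:

* **Rotation pulse.** The gyroscope-y peak is `peak_gain_dps` (90 °/s per
  m/s) × intensity × a subject gain (multiplicative, sd 0.03) × a per-throw
  jitter (sd 0.03), floored at 1525 °/s. The floor mirrors the field
  protocol: a throw that never crossed the detection threshold would not
  enter anyone's dataset, so the simulator only generates detectable
  throws. Typical peaks land near 1800–2000 °/s.
* **Deceleration burst.** The accelerometer burst peaks at `acc_gain_g`
  (2.8 g per m/s) × intensity ≈ 60 g. The low-g channel clips at ±16 g; the
  high-g channel does not. Pulse widths vary per throw (sd 15 %), so the
  time a clipped channel spends at full scale is a poor velocity proxy
  while the unclipped peak amplitude remains a clean one — this is the
  mechanism by which high-g features outperform low-g features for velocity
  regression, and it is asserted as a direction-of-effect test.
* **Intensity vs label.** The radar-style velocity *label* is drawn from the
  condition Normal; the signals are driven by label + N(0, 0.9 m/s). That
  0.9 m/s sensor-side noise sets the analytic floor for regression: the
  best possible MAE is 0.9·√(2/π) ≈ 0.72 m/s, and the LOSO requirement is
  to stay within twice that floor.
* **Condition signatures.** Wind-up writes on gyroscope-x (circle: one
  broad 0.6 s lobe; whip: a sharp 0.15 s biphasic pulse — so the x-axis
  mean and sum separate the two). Approach writes on the low-g
  accelerometer before the burst (running: a 2.5 Hz step oscillation;
  jumping: a flight phase where the accelerometer reads ≈ 0 g followed by a
  landing spike; standing: quiet).

The simulator deliberately does **not** emulate sensor orientation drift,
soft-tissue artefact, magnetometer output, game-like unconstrained movement
between throws, or passes vs shots. Passing tests therefore demonstrate
that the pipeline's machinery is correct and recovers structure that is
present; they do not demonstrate field accuracy on real athletes, whose
signals are noisier and whose classes overlap far more.

## Problem sizes and seeds

All randomness flows through explicit seeds; regenerating any session with
the same configuration is bit-identical. The test suite runs the full
17-subject study once for the parameter-recovery checks (2 s and 3 s
windows, single-point hyperparameter grids) and uses 2–6-subject studies
elsewhere; the null-distribution checks use 2000 simulated tables for the
ANOVA size and the Holm family-wise error. `scripts/acceptance.R` repeats
the 17-subject analysis end-to-end — detection, feature extraction, LOSO
classification and regression in both ranges, ANOVA and contrasts — from a
single command-line seed.

## Known limitations

* The 201-feature catalogue is one consistent reconstruction of the named
  statistic families; the field has no canonical enumeration. It is
  versioned (`attr(feature_catalogue(), "version")`) so alternatives can be
  swapped in without touching downstream code.
* "Power" is taken as the mean of squares; band-limited or integrated
  readings of signal power would differ by a constant factor at fixed
  window length.
* Detection assumes the positive y-direction carries the throw rotation;
  `use_abs` covers the opposite mounting but no automatic polarity check is
  attempted.
* The per-subject response entering the ANOVA is one value per subject per
  model × range cell (macro F1 or MAE); alternative nestings of the LOSO
  folds into the design are possible but not implemented.
* The four hyperparameter grids are small and desk-scale by design; they
  are arguments, not constants, and widen trivially.
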