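---
title: "Estimating ACGIH lifting risk zones from five wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ACGIH lifting risk zones from five wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftzone)
```

## The problem

The ACGIH Threshold Limit Values (TLV) for manual lifting assess a
two-handed lift by where the hands are at the lift origin: the vertical
height $V$ of the hand centre above the ground and the horizontal
distance $H$ from the mid-point between the ankles to the mid-point
between the hands.  The $(V, H)$ plane is divided into a grid of 4
vertical bands (V1 top, 1.45–1.70 m, down to V4, 0–0.5 m) by 3
horizontal bands (H1 near, 0–0.25 m, out to H3, 0.457–0.712 m), giving
12 lifting zones, which practitioners often collapse into three risk
levels: zones 4–5 low, 6–9 medium, and 1–3 and 10–12 high.

Measuring $V$ and $H$ by tape in the field interrupts work.  This
package implements an alternative: estimate them from five
body-worn inertial measurement units (IMUs) on the forearm, upper arm,
back, thigh and calf, each providing a tri-axial gyroscope and
accelerometer at 25 Hz, and classify each lift into a zone and risk
level.  Because the original laboratory data set (10 subjects × 3
repetitions × 12 zones = 360 trials against optical motion capture) is
not publicly deposited, the package also ships a seeded synthetic-trial
simulator that reproduces that design with known ground truth, so every
claim the package makes can be checked by parameter recovery.

## The model

All kinematics are projected onto the sagittal plane.  Each segment $s$
has a length $L_s$ and an inclination-from-vertical angle $\theta_s$
(positive forward).  Stacking the chain from the ankle up — calf
assumed vertical, so it contributes its full length and no horizontal
term — and hanging the arm down from the shoulder:

$$V = L_{back}\cos\theta_{back} + L_{thigh}\cos\theta_{thigh} + L_{calf}
    - L_{UA}\cos\theta_{UA} - L_{FA}\cos\theta_{FA}$$

$$H = L_{UA}\sin\theta_{UA} + L_{FA}\sin\theta_{FA}
    + L_{back}\sin\theta_{back} - L_{thigh}\sin\theta_{thigh}$$

The thigh term is subtracted in $H$ because a positive thigh angle puts
the knee forward of the hip, moving the hip (and everything above it)
backward.  The arm terms are subtracted in $V$ because the arm hangs
downward; a hand above the shoulder simply needs $|\theta| > \pi/2$,
which is allowed, not clamped.  Postures with the hands behind the
ankles produce negative $H$; the zoning layer clamps out-of-range
values to the nearest band and flags them rather than refusing to score
them.

Two anthropometric variants feed these equations:

* **ratio model** — only the forearm is measured; the other lengths are
  forearm × population ratios (defaults from the Drillis–Contini
  stature proportions, re-expressed relative to the forearm: upper arm
  1.27, back 1.97, thigh 1.68, calf 1.69).  The ratio table is an
  argument, not a constant, because the population values appropriate
  to a cohort may differ.
* **ratio + length model** — all five segments are measured
  individually.

## Sensor fusion

Gyroscope integration alone drifts without bound under a constant rate
bias $b$; the accelerometer supplies an absolute (but noisy) gravity
reference.  The package fuses them with a first-order complementary
filter,

$$\theta_k = \alpha\,(\theta_{k-1} + \omega_k \Delta t)
  + (1-\alpha)\,\mathrm{atan2}(a_{x,k}, a_{z,k}),$$

initialized from the first accelerometer sample.  This design was
chosen over a Kalman filter because it is the simplest filter that
achieves the stated goal (drift correction against the gravity
reference) and it is analytically checkable: for a static sensor the
steady-state error under bias $b$ is exactly
$\alpha b \Delta t/(1-\alpha)$, which the tests assert to $10^{-6}$.
With the defaults $\alpha = 0.98$ at 25 Hz, a typical consumer-grade
bias of 0.02 rad/s leaves a bounded error of about 0.04 rad instead of
a drift of 1.2 rad/min.  $\alpha = 0$ reproduces the accelerometer
inclination pointwise; $\alpha = 1$ is pure integration.

Samples whose acceleration magnitude falls outside 2–25 m/s²
(free-fall-like or impact-like, when the direction of the measured
specific force is not gravity) are flagged and bridged by the gyro-only
prediction.  Off-plane motion (e.g. forearm pronation) is deliberately
not modelled: the estimator is two-dimensional by design, and overhead
lifts, where pronation is largest, are exactly where this class of
planar model is known to fail.

## Lifting-event detection

No training data exist to rebuild a learned detector, so detection is
rule-based and fully parameterized: the forearm's sagittal angular rate
is smoothed with a centred 5-sample moving average, and an event opens
when the smoothed speed holds at or above 0.3 rad/s for 0.3 s and
closes when it stays below 0.1 rad/s for 0.4 s (hysteresis); events
shorter than 0.5 s are discarded.  Raising the opening threshold can
only remove events, and shifting all timestamps shifts event boundaries
exactly — both are asserted as properties.

A lift is scored at its *origin*.  The detector reports, alongside the
event boundaries, the last sample below the closing threshold at or
before the event start.  Scoring exactly at the threshold-crossing
`t_start` would sample the posture ~2–3 % into the movement (threshold
plus smoothing delay) and bias $V$ toward the destination posture by up
to ~2 cm; backtracking to the last quiet sample removes that bias while
keeping the event boundaries themselves unchanged.  Whether a lift
should be scored at its start or end is genuinely ambiguous in general;
the pipeline takes the **last** detected event in a trial as the lift
proper (earlier events are the preparatory reach toward the origin) and
scores it at its origin instant.

## The synthetic experiment

The simulator emulates the laboratory design: 10 subjects × 3
repetitions × 12 zones, order randomized per subject, one master seed
determining everything.

* **Subjects.**  Stature ~ N(1.70 m, 0.09 m) truncated to
  [1.50, 1.95].  True segment lengths are Drillis–Contini fractions of
  stature jittered multiplicatively per segment with sd 8 % — a
  realistic inter-individual proportion variability, and the mechanism
  that separates the two models: the ratio model's population table
  cannot know an individual's deviations, while the measured-lengths
  model sees them (through a 5 mm tape-measurement error).
* **Targets.**  Each trial aims at the centre of its zone's $(V, H)$
  rectangle with ±3 cm uniform jitter, kept 1.5 cm inside the zone
  edges.  When a subject cannot reach that point (short subjects in the
  high/far zones), the target slides within the rectangle toward a
  subject-specific reachable anchor, then falls back to a grid scan of
  the rectangle — mirroring how the laboratory staging adapted
  positions to subject height.  A zone whose entire rectangle is out of
  reach is skipped with a warning (rare; the default design normally
  keeps all 360 trials).
* **Postures.**  The lift-origin posture is solved by a stoop
  heuristic (trunk flexion ramps in below hip height, thigh flexion
  below knee height) plus exact two-link inverse kinematics for the arm
  (elbow-down branch); when the heuristic trunk angle leaves the target
  outside the arm's annulus the trunk angle moves to the nearest
  feasible value on a fine grid.  The solver is deterministic and its
  forward kinematics reproduce the target to machine precision (tested
  at $10^{-9}$ m).
* **Trajectories.**  Each trial is rest (1 s) → minimum-jerk reach to
  the origin (1.5 s) → hold (1 s) → minimum-jerk lift to a carry
  posture (1.5 s) → rest (1 s), all segments sharing one phase clock at
  25 Hz.  The carry posture brings the forearm to horizontal unless the
  origin already holds it high; this guarantees the lift phase always
  has enough forearm excursion to be detectable (a mid-height, close-in
  lift otherwise rotates the forearm barely at all).  Ground truth is
  the noise-free forward kinematics at the end of the reach — the lift
  origin.
* **Sensors.**  Gyro = finite-difference of the angle + per-trial
  constant bias (N(0, 0.02 rad/s) by default, or a fixed magnitude for
  dose-response sweeps) + white noise (sd 0.01 rad/s); accelerometer =
  gravity projected through the angle + white noise (sd 0.2 m/s²).
  Optionally a fraction of samples is masked and carried forward to
  emulate missing motion data.

What the simulator does *not* emulate matters for interpreting results:
the accelerometer carries no linear-acceleration component, so the
gravity reference is cleaner than reality during movement; there is no
forearm pronation, sensor misalignment drift, or soft-tissue artefact;
and postures are exactly planar and symmetric.  Passing tests therefore
demonstrate that the estimation pipeline is correct and well-behaved
under controlled violations (bias, noise, anthropometric mismatch) —
not that field accuracy would match the laboratory figures.

## Evaluation

Every trial scores 0 or 100 %: the predicted zone either equals the
ground-truth zone or it does not.  The package reports the 12-zone
accuracy, per-axis V/H band accuracies, a per-subject agreement grid
(0–3 matched repetitions per zone, the heat-map view), mean signed
errors by band, and a 3×3 grouped-risk confusion matrix with per-class
precision (diag/column from raw counts), recall (diag/row), F-score
(harmonic mean, 0 when both vanish), their unweighted macro averages,
and the class-size-weighted recall trace/total.  Row-normalized rates
are reported alongside the raw counts because the three risk classes
have 60/120/180 trials in the full design; precision is always computed
from raw counts.  Trials with no detected lift are excluded from the
counts and reported separately.

Numerical conventions: band intervals are lower-closed and upper-open
with the top band closed (so 0.5 m is V3, 1.45 m is V1); rates and
metrics are rounded to two decimals and accuracies to whole percentages
only at the reporting layer.

## Problem sizes and reproducibility

The test suite and the acceptance script run desk-scale versions of the
experiments: the full 360-trial design for the noise-free recovery and
the two-model comparison, and 10 seeds × 24 trials per level for the
gyro-bias sweep over {0, 0.02, 0.05, 0.1} rad/s — the sweep turns the
other noise sources and the measurement error off so the dose–response
in the median $|V|$ error isolates the swept factor.  All randomness
flows from one master seed; identical seeds give byte-identical
simulated streams, results tables and reports.

## Known limitations

* The planar model cannot represent pronation or lateral asymmetry;
  overhead (V1) lifts are its known weak point.
* The calf is assumed vertical; deep squats violate this and shift $V$.
* The population ratio table is a single default; cohort-specific
  tables should be substituted where available.
* The detector assumes discrete lifts separated by quiet periods; it
  has no notion of carrying, walking or other activities.
* The TLV weight-limit lookup itself (allowable mass per zone,
  frequency and duration) is out of scope; the package stops at the
  zone and risk level.
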