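---
title: "Quantifying upper-limb function with a wrist-worn IMU during the ARAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying upper-limb function with a wrist-worn IMU during the ARAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iarat)
```

## The problem

The Action Research Arm Test (ARAT) scores 19 standardized object-handling
tasks (Grasp, Grip, Pinch and Gross-movement sections) on a 0-3 ordinal
scale, to a maximum of 57. The scale is quick and well validated, but its
rating is subjective, it suffers a ceiling effect in mildly impaired
people, and a single per-task score says nothing about *which part* of the
movement is abnormal. Instrumenting the test with a single inertial
measurement unit (IMU) on the wrist — a tri-axial accelerometer and
gyroscope sampled at 50 Hz, with per-sample orientation from the device's
onboard estimator — lets each task be decomposed into sub-movements
(reaching, manipulation, transport, release, return) and described with
continuous kinematic quantities instead of a 4-level score. `iarat`
implements that pipeline end to end, together with the clinical-score
analyses that accompany it and a synthetic movement generator that makes
every stage testable against known ground truth.

## Segmentation model

Each task is segmented from two signals:

* the **angular-speed norm** $\Omega(t) = \lVert\boldsymbol\omega(t)\rVert$,
  computed after smoothing each gyroscope axis with a 4th-order zero-lag
  low-pass Butterworth filter at 2.5 Hz (filtering is per axis, before the
  norm, so the zero-phase property holds on each component);
* the **gravity-free vertical acceleration**, obtained by rotating the
  specific force into a global frame (z vertical, up) with the per-sample
  rotation matrix and subtracting $(0,0,g)$, $g = 9.81\ \mathrm{m/s^2}$.

$\Omega(t)$ of a Grasp/Grip/Pinch item shows three bell-shaped lobes —
reaching, transport, return — separated by low-speed dwells (manipulation
and release). Movement windows are found automatically: samples with
$\Omega > \theta\,\Omega_{max}$ form runs, runs closer than `merge_gap`
are merged, and the 2 (Gross items) or 3 longest runs are kept; a manual
rough partition can be supplied instead, mirroring semi-automated use.
Within each window, the lobe onset/offset are the crossings of the
threshold $\theta\,\Omega_{max}$, with $\theta = 0.25$ as the operating
value from the candidate family $\{0.15, 0.20, 0.25, 0.30\}$; an error
analysis against reference instants (`threshold_error_analysis()`)
reports, per instant type and threshold, the mean and SD of the absolute
timing error, and flags the threshold minimizing the all-instants mean —
the rule by which the operating value is selected. The return phase ends
at the last prominent peak of the vertical acceleration, the hand-table
contact.

Design choices worth stating explicitly:

* **Scope of $\Omega_{max}$.** "Fraction of the maximum angular speed" can
  be read task-globally or per movement portion. Both are implemented
  (`omega_max_scope`), the default being the task-global maximum; tests
  exercise both.
* **Sub-sample crossing interpolation.** Snapping boundaries to the first
  sample beyond the threshold adds up to one sample (20 ms) of one-sided
  bias; together with the slight lobe-widening of the 2.5 Hz zero-lag
  filter (about 13 ms at $\theta=0.15$ for a 0.63 s lobe) that would push
  the worst-case boundary error beyond one sample even on noise-free
  signals. The default therefore interpolates the crossing linearly
  between the two bracketing samples (`interp = TRUE`), keeping noise-free
  errors within one sample across the whole threshold family; the literal
  sample-snapped rule remains available.
* **`merge_gap` default (0.05 s).** Run merging exists to repair brief
  noise-induced dips inside one lobe. The gap must stay below any
  physiological dwell — healthy manipulation dwells are on the order of
  0.15 s — so the default is 3 samples at 50 Hz.
* **Peak prominence (0.5 m/s^2).** "Last peak" needs a definition; the
  impact transient of hand-table contact is several m/s^2 even in gentle
  movement, while tremor and sensor noise stay well below 0.5 m/s^2 in
  prominence. If no qualifying peak exists the return offset falls back to
  the threshold crossing, with a warning.
* **Tie-breaking.** Equal-duration runs keep the earlier one;
  deterministic behaviour is part of the contract.

## Metrics

Per phase and per whole task (first onset to return termination), two
quantities are computed:

* **Duration** $D$ = offset − onset.
* **Jerk index**
  $JI = \ln\!\left(\dfrac{\overline{\lVert \dot a\rVert}}{\overline{\lVert a\rVert}}\, D\right)$,
  with $a$ the gravity-free global acceleration and $\dot a$ its central
  finite difference (one-sided at edges). The ratio normalizes out
  amplitude, and multiplying (not dividing) by $D$ makes the index
  dimensionless — division would leave units of $s^{-2}$ and cannot land
  near the magnitudes healthy tasks actually show. The natural log is used
  for the same reason: at 1-2 Hz movement content and 2 s tasks,
  $\ln(2\pi f D)$ sits near 3, where a base-10 convention would sit near
  1.3. For a pure sinusoid at frequency $f$ over an integer number of
  periods, $JI = \ln(2\pi f D)$ exactly, which the tests use as a closed
  form. Acceleration is not smoothed before differentiation by default;
  `accel_cutoff` exposes optional pre-smoothing.

**Z-scores.** Every cell (parameter $P$, item $j$, phase $k$) is
standardized against the control cohort:
$Z_{P,i,j,k} = (P_{i,j,k} - \bar P_{co,j,k})/\sigma_{co,j,k}$, with the
SD on $n-1$ degrees of freedom (normative statistics from a finite
control sample). Subject-level aggregates (`subject_zscores()`) average
the parameter across items first and z-score that mean against the
distribution of the same mean in controls (*mean-then-z*); the alternative
(z-then-mean) weights items by the inverse control SD, which is not what
"z-score of the mean item duration" describes. Section summaries do the
same per ARAT section.

## Clinical scores

The embedded tables `ms_clinical()` and `ms_demographics()` transcribe the
published 21-subject MS cohort. Three conventions matter:

* **Peg-test conversion.** One Nine Hole Peg Test trial moves 9 pegs;
  `pegs_per_minute()` computes $60 \cdot \mathrm{round}_2(9/t)$ — the
  per-second rate rounded to two decimals before scaling — which
  reproduces every printed rate except one anomalous row (S18, kept as
  printed in the fixture and excluded from conversion tests). Subjects
  unable to complete the test get rate 0, which keeps the score defined
  for the whole cohort and is the reason pegs/min (not seconds) enters
  the clustering.
* **Clustering features.** The impairment clustering uses ARAT total,
  9HPT pegs/min and the FTRS postural+intention sum, standardized across
  the cohort, with Euclidean distance and UPGMA (average linkage) —
  `stats::hclust` does the tree, `cutree` the partition. These are the
  only representations defined for every subject.
* **Medians.** Group summaries use the average-of-two-central-order
  statistics convention for even n, which matches every printed median.

## Nonparametric statistics

Group comparisons use a rank-based battery: Mann-Whitney U (two
independent groups), Kruskal-Wallis (three or more), Friedman (repeated
measures across ARAT sections), Holm's step-down adjustment for post-hoc
families, and Spearman correlation for validity analyses. Two
implementation choices:

* **Exactness crossover.** The study's group sizes (12 vs 21; subgroups
  12/5/4) straddle where exact small-sample p-values matter.
  `mann_whitney()` enumerates all group assignments (valid under ties)
  when the pooled n is at most 16, and otherwise uses the normal
  approximation with tie and continuity corrections; `spearman()`
  enumerates all permutations up to n = 9 and uses the t approximation
  beyond. Kruskal-Wallis, Friedman and Holm wrap the base-R
  implementations.
* **Post-hoc pattern.** After a significant Kruskal-Wallis, all pairwise
  Mann-Whitney comparisons are Holm-adjusted; after a significant
  Friedman, pairwise two-treatment Friedman tests (a paired comparison on
  within-block ranks) are Holm-adjusted.

All reported p-values are two-sided.

## The synthetic generator

No raw recordings accompany the study, so `simulate_task()` generates
them with exact ground truth. The angular-speed profile is a sum of
minimum-jerk speed bells, $v(\tau) \propto 16\,\tau^2(1-\tau)^2$ — the
canonical shape of point-to-point reaching — whose threshold crossings
have the closed form $\tau = \tfrac12\bigl(1 \mp \sqrt{1-\sqrt c}\bigr)$
for threshold fraction $c$. Key constructions:

* **Consistent orientation.** The wrist rotation is about a fixed global
  axis with angle equal to the integrated angular speed, so the gyroscope
  reading and the rotation matrices describe exactly the same motion, and
  `free_acceleration()` recovers the generator's global acceleration to
  1e-9 in the noise-free case.
* **Calibration in segmented time.** Movement-lobe supports are sized so
  that the 0.25-threshold crossing-to-crossing span equals the target
  phase duration (healthy defaults: reaching 0.45 s, transport 0.66 s,
  return 0.67 s; the return lobe ends at the impact transient, so its
  factor is $1-\tau_{0.25}$). Dwell targets (manipulation 0.14 s, release
  0.21 s for controls) are realized as the *pause between lobe supports*:
  the speed norm rests near zero for that long, every threshold in the
  family separates the lobes cleanly, and crossings are uncontaminated by
  the neighbouring lobe. The geometric price is that *segmented* dwell
  durations additionally include the sub-threshold lobe tails (~0.26 s at
  the defaults); group *contrasts* in dwell duration — the quantity the
  discrimination analyses rest on — are preserved additively. A dwell
  explicitly requested as zero (mean 0, SD 0) instead collapses the two
  crossings onto each other, the degenerate contiguity case; note that
  threshold segmentation cannot separate lobes in that regime, which is a
  property of the method, not a bug of the generator.
* **Impairment model.** Mild kinematics use the published sub-movement
  durations of MS subjects scoring a full 57 on ARAT; the severe
  manipulation dwell is 2.74x control, matching the reported 174% median
  duration increase of the most affected sub-movement; moderate sits
  between. Peak angular speeds scale down mildly with severity (0.95 /
  0.85 / 0.75), and intention tremor — a 3.5-5 Hz narrow-band oscillation
  with random phase — is added to the acceleration with an envelope that
  ramps in over the final 30% of each object-directed lobe and holds
  through the following dwell, the kinematic signature of tremor that
  worsens at the end of goal-directed movement. Tremor amplitudes are 0 /
  0.3 / 0.8 / 1.5 m/s^2 by group.
* **Sensor model.** Gravity is added in the global frame, everything is
  mapped to the sensor frame with the inverse rotation, and white noise
  (0.05 m/s^2, 1 deg/s) is added per axis. A Gaussian vertical transient
  (8 m/s^2, sigma 30 ms) marks hand-table contact. Within-subject
  phase-duration SD is 10% of the mean and between-subject variation is
  log-normal with sigma 0.08 — values chosen once as typical of repeated
  upper-limb movements.
* **Clinical scores.** `simulate_cohort()` maps each severity grade to
  uniform draws within the corresponding published cluster's non-outlier
  ranges (controls: ARAT 57, peg time ~N(19, 2) s, the healthy reference
  value); two of the severe subjects are drawn unable to complete the peg
  test, mirroring the real cohort.
* **Gold-standard oracle.** `simulate_marker_oracle()` rebuilds the wrist
  speed at 200 Hz from the same lobes, filters it with the
  motion-capture convention (order 5, zero lag, 6 Hz) and applies the
  20%-of-peak-speed rule per portion, providing the reference instants
  for the threshold error analysis.

What the generator does **not** emulate: finger kinematics (the wrist
sensor cannot see them either), orientation-estimator drift and dynamic
error, soft-tissue artifacts, multi-axis rotation paths, pathological
movement fragmentation (extra velocity peaks), or magnetometer data.
Passing tests therefore demonstrate correctness of the *pipeline
computations* under realistic signal morphology, not clinical validity on
real patients.

## Numerical choices

* Zero-lag filtering pads each end with `3 * order` samples of odd
  (point-symmetric) reflection, and each causal pass subtracts the
  starting level first (unit DC gain restores it), which removes the IIR
  start-up transient exactly for signals at rest at the boundaries — a
  constant series filters to itself bit-exactly.
* Noise-free verification uses the deterministic reference movement (all
  kinematic SDs zero). Randomly drawn short lobes (< 0.6 s) widen a few
  tenths of a sample beyond the one-sample bound under the 2.5 Hz filter;
  that is a property of filtering short lobes, documented rather than
  hidden behind a looser tolerance.
* Degenerate statistics (all values tied) return p = 1 with an explicit
  degenerate flag instead of NaN; zero-length manipulation/release phases
  get duration 0 and an undefined (NA) jerk index, excluded from
  aggregates.
* Friedman comparisons across sections drop sections undefined for a
  phase (Gross items have no manipulation/release) and require at least
  two complete columns.

## Problem sizes

The test-suite and verification runs use cohorts of 12 controls + 12/5/4
MS subjects (the study's group sizes) on 2-6 items per subject, 100
replicates for the discrimination power check and 50 seeds for the
severity-recovery correlation, 60 simulated tasks for the threshold error
analysis, and 100 seeds for the round-trip and duration-recovery checks —
sizes chosen so every property is exercised at the study's own scale
while the full suite stays fast.

## Limitations

Real recordings may violate the generator's cleanest assumptions: severely
impaired subjects can fail to reach $0.25\,\Omega_{max}$ in a lobe
(raising an explicit `phase_below_threshold` error rather than guessing),
concatenated multi-item recordings are out of scope, and the semi-automated
manual partition is supported but not emulated. The clustering and
conversion results on the embedded clinical tables are exact
reproductions; all sensor-side cohort results are simulation analogues.
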