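---
title: "Methods: turning detection from a lower-back 6DOF IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turning detection from a lower-back 6DOF IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turndetect)
```

## The problem

A single inertial unit on the lower back (near the body's centre of mass)
is the most practical configuration for continuous mobility monitoring in
older adults and people with Parkinson's disease. Turns — heading changes
of roughly 45° and more completed within seconds — are clinically
informative events: their number, magnitude, duration and direction relate
to balance capacity and fall risk, and they change with disease state and
medication. The task this package solves is to go from raw accelerometer
and gyroscope samples to a list of turn events, and to quantify how well
that list agrees with a reference annotation.

Magnetometers are deliberately not used: indoor environments are full of
ferromagnetic disturbances, so heading is tracked by gyroscope integration
alone and the known price — slow yaw drift from gyroscope bias — is
accepted and characterised rather than corrected.

## Attitude estimation

The sensor-to-global rotation matrix $R$ is stored with the global axes as
rows expressed in the sensor frame, so $v_G = R\,v_S$.

**Initialisation.** The recording must begin (or at least contain) a
quasi-static period. The earliest run of `stable_window_samples` (default
5) consecutive accelerometer samples whose per-axis peak-to-peak amplitude
is below `stable_pp_threshold` (default 0.2 m/s²) defines the gravity
estimate $g$ = the window's mean accelerometer vector. At 128 Hz five
samples span only a few hundredths of a second, so any quiet standing at
the start suffices. The rows of the initial $R$ are built as

$$Z = g/\lVert g\rVert,\qquad Y = Z \times X_{seed},\qquad X = Y \times Z,$$

with $X_{seed} = (1,0,0)^T$ (the choice is arbitrary — it only fixes the
yaw origin, which is 0 by construction; if gravity is parallel to the
sensor x axis the seed falls back to $(0,1,0)^T$). All rows are normalised;
the result is orthonormal with determinant $+1$. The stability criterion is
evaluated per axis (evaluating it on the norm instead is a defensible
alternative; per-axis is slightly stricter). If no window in the whole
recording qualifies, initialisation fails loudly — every downstream angle
depends on it, so guessing a frame would silently corrupt all results.

**Propagation.** Each gyroscope sample $\omega_S$ (rad/s) is mapped to the
global frame, $\omega_G = R\,\omega_S$, and advances the rotation by the
Rodrigues axis–angle matrix $T(\omega_G)$ about the unit axis
$\omega/\lVert\omega\rVert$ with angle $\theta = \lVert\omega\rVert/f_s$:

$$R_{new} = T(\omega_G)\,R_{old}.$$

Two numerical points. First, the Rodrigues matrix requires a *unit* axis;
using raw rate components would give a non-orthogonal matrix. Second, the
global-frame left-multiplication is algebraically identical to the
body-frame right-multiplication $R_{old}\,T(\omega_S)$ (because
$T(R\omega) = R\,T(\omega)R^T$); the package implements the former and
keeps a pure-R propagator with both conventions as a test cross-check
(agreement to $10^{-10}$ per sample is asserted). Integration is
left-endpoint rectangular: the gyro sample at the start of each $1/f_s$
interval advances the orientation across it. Orthonormality is monitored
every sample; drift beyond $10^{-6}$ triggers a Newton/polar
re-orthonormalisation ($R \leftarrow 1.5R - 0.5RR^TR$, the standard
strapdown projection) and is counted on the returned track. In practice
double-precision drift stays below $10^{-6}$ for hours of signal.

**Euler extraction.** Angles use the intrinsic Z-Y-X (yaw–pitch–roll)
convention; the convention matters little here because only yaw is consumed
downstream and yaw is convention-stable for a near-upright sensor. Wrapped
yaw lies in $(-180°, 180°]$; the unwrapping step removes the ±360° seam
jumps, since a heading crossing ±180° is not a turn. Gimbal proximity
(|pitch| > 89.9°) is flagged but cannot occur for a lower-back mounting.

## Turn detection

**Segmentation.** The unwrapped yaw trace is cut at its direction
reversals: a right turn starts where yaw changes from increasing to
decreasing and ends at the opposite change, and vice versa for left turns.
Segments therefore tile the trace — the end of one is the start of the
next — and each is maximal monotone. Two boundary decisions are the
package's own: segments touching the recording boundaries are eligible
turns (discarding them would silently lose events), and runs of *exactly*
constant yaw become their own zero-magnitude segments. The latter arises
only in noise-free synthetic signals (real noise makes exact ties
measure-zero) and keeps quiet gaps from being absorbed into adjacent
turns, which would otherwise inflate their durations; an entirely constant
trace yields no segments.

**Hesitation merging.** People — particularly with Parkinson's disease —
often interrupt a turn briefly. Such an interruption would split one
physical turn into two detected ones. The rule: an interruption of
duration < `hesitation_max_duration` (0.5 s) whose magnitude is below
`hesitation_max_fraction` (10%) of **both** neighbouring movements, each of
which must exceed `hesitation_min_neighbor` (10°) with the same sign, is
merged with its neighbours into one segment whose magnitude is the **net**
yaw change from start to end (not the sum of absolute sub-magnitudes).
All three boundaries are strict inequalities (a 0.5 s interruption or one
at exactly 10% does not merge); strictness is asserted by the boundary
test-suite. Merging scans left to right and repeats to a fixed point, so
chains of hesitations collapse deterministically into a single turn.

One generalisation over the plain three-segment formulation: at full
sampling resolution, sensor noise splits the instant of a physical
hesitation into a chain of minute reversals (fractions of a degree each),
so the literal previous/next neighbours of the dip are micro-segments that
can never satisfy the >10° condition. The rule is therefore applied to the
whole *gap* of sub-threshold segments between two qualifying neighbours:
total gap duration under the limit, every gap segment under the neighbour
fraction. For a single-segment gap this is exactly the classic rule; with
it, the noisy hesitation scenario is resolved correctly (one event per
scripted turn), without it almost none are.

**Filtering and metrics.** A merged segment becomes a turn event if its
absolute magnitude is at least `magnitude_threshold` (default 90°,
inclusive, sweepable over 45°–110°) and its duration lies within
`duration_min`–`duration_max` (0.1–10 s, inclusive). Duration is the
horizontal extent of the segment, magnitude the vertical extent of the yaw
trace over it. Direction is determined by the trapezoid-rule integral of
the vertical global-frame angular rate over the event; for any accepted
turn it coincides with the sign of the segment's yaw change (asserted as an
internal-consistency property). The mapping from sign to the words
"left"/"right" is exposed as `direction_convention` because it depends on
the sensor's mounting orientation, which the data alone cannot reveal: the
default maps a positive integral to a right turn, and the mirrored
convention is available. Internal consistency (detected direction vs
scripted direction under one convention) is testable; the absolute label is
not, without hardware in hand.

## Validation statistics

Matching detected to reference events is one-to-one and greedy by absolute
midpoint difference: pairs are eligible when their intervals overlap or
their midpoints differ by at most `match_tolerance` (2.5 s, chosen to cover
the spread of detection-time differences seen against human annotation),
nearest pairs accepted first, exact ties broken toward the earlier detected
event so results are deterministic. Matched pairs are true positives;
unmatched detections, false positives; unmatched references, false
negatives.

Event detection has no natural non-event unit, so the true-negative count
is a *definition*, not a measurement: here, the number of maximal reference
gaps (including the two boundary gaps) at least `duration_min` long that
contain no detected-turn midpoint. The definition is isolated in
`count_true_negatives()` so alternatives (fixed-length windows, say) can be
swapped without touching anything else; reported specificity and kappa
inherit whatever definition is used, which is worth remembering when
comparing absolute numbers across studies.

From the confusion counts: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
accuracy (TP+TN)/N, PPV TP/(TP+FP), NPV TN/(TN+FN) — standard definitions,
zero denominators yield `NA` rather than 0. Cohen's kappa uses
$p_o = (TP+TN)/N$ and
$p_e = [(TP+FP)(TP+FN) + (FN+TN)(FP+TN)]/N^2$; it is invariant under
exchanging the raters and equals 1 exactly when FP = FN = 0. Detection-time
agreement is summarised Bland–Altman style — mean difference, SEM
(SD/$\sqrt{n}$), limits of agreement mean ± 1.96 SD — on the *start-time*
differences of matched pairs (midpoint or end-time differences are a
one-line change; start times are what annotators flag most reliably).
Statistics are kept at full precision internally; two-decimal
round-half-away-from-zero is applied only in printed reports.

## The synthetic-recording generator

The generator renders a scripted phase sequence (quiet standing / turns
with optional hesitations) into sensor signals, providing exact ground
truth for every other module's tests.

* **Yaw trajectory.** Each turn's angular-velocity profile is analytic —
  raised-cosine by default (zero velocity and acceleration at the edges,
  as human turns approximately have), trapezoid as an alternative. Profiles
  are evaluated at sample-interval midpoints (never exactly zero inside a
  movement) and rescaled so the *discrete left-endpoint integral* equals
  the scripted magnitude exactly, matching the estimator's integration
  scheme; ground truth is therefore exact rather than approximate, and
  recovery tolerances are meaningful. Hesitations are brief
  opposite-direction dips; the moving portions are scaled up so the net
  magnitude stays exactly as scripted.
* **Sensor model.** The sensor is mounted with a static tilt (default 10°,
  a plausible lower-back placement; roll/pitch sway is not modelled because
  the algorithm consumes only yaw). The gyroscope reads the body-frame
  rate plus a constant bias plus Gaussian white noise; the accelerometer
  reads gravity in the sensor frame plus Gaussian white noise. Defaults —
  128 Hz, gyro noise SD 0.5 °/s per sample, accel noise SD 0.05 m/s²,
  zero bias — are conservative consumer-IMU values. A single integer seed
  controls every draw; identical seeds give bit-identical fixtures.
* **Not modelled.** Step impacts and gait oscillation, trunk sway, linear
  acceleration during movement, temperature-dependent bias, quantisation.
  Passing the recovery suite therefore demonstrates the pipeline's
  correctness and its noise robustness, not performance on real gait data —
  the accelerometer is only ever used for the initial alignment, which is
  why omitting gait dynamics is acceptable for testing this particular
  algorithm.

Problem sizes used by the test-suite and the acceptance script are the
package's own choices: 200 scripted turns (~24 min of signal) for the
recovery statistics, 60 s for loop closure, 90 min for the drift model.

## Known limitations

* **Gyro-bias drift.** A constant vertical bias $b$ produces an unwrapped
  yaw drift of exactly $b\,t$ (the drift-model check measures the ratio at
  1.000 over 90 min). Drift is slow compared with turning dynamics and a
  monotone drift ramp fails the 10 s duration bound, so it creates no
  false turns at realistic bias levels; it does make the *absolute* heading
  meaningless over long recordings, which is irrelevant here because only
  yaw *changes* are analysed.
* **Slow, wide-radius turns.** A turn stretched over more than 10 s (seen
  in medicated Parkinson's patients walking wide arcs) is rejected by the
  duration window, or split into sub-threshold pieces — an inherent
  failure mode of magnitude/duration thresholding, reproduced by the
  `wide_radius` scenario.
* **Boundary resolution under noise.** The raised-cosine profile's
  velocity tails are below the gyroscope noise floor for a few hundredths
  of a second at each turn edge, so the detected extremum sits slightly
  inside the scripted interval: at the default noise (0.5 °/s) the
  recovery suite measures a mean absolute duration error of ~0.11 s
  (magnitude error ~0.3°, detection-time mean difference ~0.06 s). This is
  an information limit, not an implementation artefact — over the masked
  tails the yaw accrues far less than the integrated noise — and it shrinks
  with quieter gyros or sharper velocity profiles. An optional low-pass of
  the yaw trace is deliberately **off** by default: gyro integration
  already smooths white noise, and the unsmoothed trace is what the
  segmentation rules are defined on.
* **Left/right labelling.** Without knowing the physical mounting, the
  direction labels are correct only up to the configured convention (a
  mirror ambiguity); within one convention they are internally consistent
  with the yaw trace, which is what the tests assert.

## A compact demonstration

```{r demo}
suite <- scenario_suite(seed = 1)
fit <- detect_turns(suite$hesitant$recording)
fit
# every scripted hesitation merged: one event per scripted turn
nrow(fit$events) == nrow(suite$hesitant$truth)
validate_turns(fit$events, suite$hesitant$truth, span = fit$span)
```
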