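# turndetect

Turning detection and analysis from a single 6DOF inertial measurement
unit (IMU) worn on the lower back.

Turning is a demanding everyday movement: it loads dynamic balance, it is
linked to fall risk, and it degrades early in Parkinson's disease. A
lower-back accelerometer + gyroscope unit can monitor turning continuously
outside the laboratory, but raw inertial signals do not expose turns
directly — the sensor's orientation must be tracked and the heading angle
segmented into discrete turn events. `turndetect` implements that pipeline
for people working on wearable-sensor mobility analysis: detection of turn
events with their magnitude, duration and direction, event-level validation
against reference annotations, and a seeded synthetic-recording generator
so the whole chain can be exercised and tested without hardware.

## The algorithm

**Attitude estimation.** The sensor-to-global rotation `R` (rows are the
global axes expressed in the sensor frame, so `v_G = R v_S`) is initialised
from the earliest quasi-static window of the recording: five consecutive
accelerometer samples whose per-axis peak-to-peak amplitude stays below
0.2 m/s². The normalised mean accelerometer vector over that window becomes
the global Z row (gravity); the X row is seeded with the sensor x axis and
the triad is completed by two cross products, so the initial yaw is 0 by
construction. Each subsequent gyroscope sample `ω_S` (rad/s) advances the
rotation by a Rodrigues axis–angle increment

    R_new = T(ω_G) · R_old,   ω_G = R ω_S,   θ = ‖ω‖ / f_s,

where `T(ω)` rotates about the unit axis `ω/‖ω‖` by `θ` (the algebraically
identical body-frame form `R_old · T(ω_S)` is kept as a cross-check).
Euler angles are extracted in the intrinsic Z-Y-X convention; only the yaw
(heading) angle is consumed downstream, after unwrapping across the ±180°
seam.

**Turn detection.** The unwrapped yaw trace is cut into maximal monotone
pieces at its direction reversals — the end of one piece is the start of
the next. A brief interruption (< 0.5 s) whose magnitude stays below 10% of
both neighbouring movements, each of which exceeds 10° in the same
direction, is a *hesitation*: it is merged so the turn counts once, with
magnitude equal to the net yaw change. Surviving segments become turn
events if their absolute magnitude reaches the threshold (default 90°,
sweepable 45°–110°) and their duration lies in 0.1–10 s. Direction comes
from the sign of the integrated vertical angular rate (the mapping between
sign and left/right is a configurable convention, since it depends on how
the sensor is mounted).

**Validation.** Detected events are matched one-to-one to reference
annotations (nearest midpoints within a 2.5 s tolerance, or overlapping
intervals). From the resulting confusion counts the package derives
sensitivity, specificity, accuracy, predictive values and Cohen's kappa,
plus a Bland–Altman summary of the detection-time differences, and a
per-threshold sweep report. True negatives — event detection has no natural
non-event unit — are counted as reference gaps that contain no detection
(an explicit, swappable definition).

## Worked example

Script two turns — the second one interrupted by a 7°, 0.3 s hesitation —
render the IMU recording, detect, and validate against the scripted truth:

```r
library(turndetect)
script <- turn_script(
  phases = list(quiet_phase(3), turn_phase(120, 2), quiet_phase(2.5),
                turn_phase(-150, 3, hesitations = list(c(0.5, 7, 0.3))),
                quiet_phase(2.5)))
sim <- render_script(script, seed = 7)
fit <- detect_turns(sim$recording)
fit$events
#>    t_start     t_end duration magnitude direction    source
#> 1 3.023438  4.960938 1.937500  119.8745     right algorithm
#> 2 7.507812 10.484375 2.976562  149.9872      left algorithm
validate_turns(fit$events, sim$truth, span = fit$span)
#> Turn detection validation (matching tolerance 2.5 s)
#>   TP 2  FP 0  TN 3  FN 0  (algorithm 2, reference 2)
#>   sens 1  spec 1  acc 1  ppv 1  npv 1  kappa 1
#>   detection time: mean diff 0.016 s (SEM 0.008 s; LoA -0.01 to 0.04 s)
```

Both scripted turns are recovered with magnitudes within a fraction of a
degree despite sensor-grade noise (gyroscope 0.5 °/s, accelerometer
0.05 m/s²); the hesitation is absorbed into its turn instead of splitting
it. `plot(fit)` draws the yaw trace with the detected events shaded, and
`threshold_sweep(fit, sim$truth)` reproduces the
one-row-per-threshold report used to pick the operating threshold.

A command-line dispatcher is installed under `inst/cli/turndetect`
(subcommands `simulate`, `detect`, `validate`, `sweep`; all thresholds
exposed as flags).

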