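---
title: "Methods: magnetometer-free motion-capture gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnetometer-free motion-capture gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmocap)
```

## The problem

Full-body motion capture for clinical gait analysis measures a subject with
up to 15 body-worn devices: either inertial measurement units (IMUs) whose
sensor fusion emits per-frame orientation quaternions, or optical
marker-cluster rigid bodies whose camera system emits per-frame rigid
transforms.  Two practical obstacles stand between raw device streams and
clinically usable gait variables:

1. **Heading, without magnetometers.**  Indoor magnetic disturbance makes
   magnetometers unreliable, but without them each IMU's orientation is
   expressed in a private global frame that shares only the gravity
   direction with the world -- its horizontal reference points in an
   arbitrary, per-sensor direction.
2. **Gait events, without extra instrumentation.**  Spatio-temporal and
   kinematic variables are defined between gait events (initial contact,
   toe-off, ...), which must be found from the kinematics themselves if no
   pressure platform or instrumented treadmill is available.

`gaitmocap` implements the computational core of a system that addresses
both, plus the test-retest reproducibility statistics used to qualify such
a system, and a parameterised walking-avatar simulator so the entire chain
can be validated end to end without hardware.

## Frames and conventions

The world frame is fixed as **X mediolateral (subject's right positive), Y
vertical up, Z anteroposterior (direction of progression positive)**.
Joint rotations are decomposed with intrinsic **rxzy** Euler order
(`R = Rx Rz Ry`), so the X component is the flexion-extension plane, the Z
component ab/adduction or tilt, and the Y component axial rotation.  The
frame was chosen so this axis-to-motion mapping holds in neutral stance; it
is a consistent reconstruction rather than a copy of any published figure.
Angles are degrees, lengths centimetres, time seconds, everywhere.

IMU sensor-fusion global frames are Z-up by hardware convention; a fixed
axis permutation applied at ingestion (one function,
`sensor_frame_to_world`) maps them into the Y-up world.

All neutral-pose bone frames are world-aligned (the neutral bone rotation
is the identity).  Euler decomposition near the gimbal singularity
(`|z| > 89.99` degrees) sets the axial component to zero and flags the
result; joint rotations in gait stay far from the pole.

## Anatomical ("Fitbody") calibration

From a single static frame of the subject in the neutral pose:

* **Heading correction (IMU only).**  Each sensor is mounted so that one
  known axis is roughly ground-parallel at a known bearing (0 or 90
  degrees) from the pelvis sensor's projected Y axis.  The residual
  `alpha = expected - measured` between that expectation and the measured
  ground-plane bearing is the per-sensor heading correction, applied as a
  rotation about the vertical axis (`heading_rotation`).  The pelvis sensor
  defines the shared frame; its own projected axis is yawed onto the world
  mediolateral axis.  The expected bearings are *signed* under the
  package's bearing convention -- this is what makes the correction
  unambiguous when sensor headings are arbitrary, and it encodes the
  mounting guideline that all lateral-surface sensors are oriented the
  same way.
* **Sensor-to-bone linking (both modalities).**  The constant
  `Rs0b = t(Rb0G) %*% Rs0G` is computed once and assumed constant while
  the device stays strapped to the segment.  Tracking then applies
  `RbiG = RsiG %*% t(Rs0b)` per frame and `Rbip = t(RpiG) %*% RbiG` for
  joint angles, with the hierarchy pelvis -> {thorax, thighs},
  thigh -> calf -> foot.

Calibration uses a single frame by default (an optional averaging window
is available via `window_s`); it deliberately contains no drift
compensation -- the intended workflow repeats the calibration before each
short capture, and the simulator can inject drift to measure its effect.

Joint-centre positions come from forward kinematics of a 20-bone skeleton
(15 instrumented) scaled to the subject: bone lengths are fixed fractions
of stature from classical segment-proportion tables in IMU mode, or are
taken from pointer-measured landmarks (trochanters, malleoli, acromions,
iliac crests) in optical mode.  The hip-centre spacing uses a simplified
fraction (0.70) of the inter-iliac-crest distance rather than a full
landmark regression; this only shifts the neutral stance width, not any
angle.

Over-ground IMU capture has no direct measurement of translation, so the
world path is reconstructed by **stance-foot pinning**: at every detected
initial contact the newly contacted ankle is anchored at its current world
position and the pelvis translates so that this ankle stays put until the
contralateral contact.  The pelvis advance per stride is then exactly the
sum of the two ankle separations at the contacts, i.e. step length left
plus right.

## Event detection

Six events per stride and side: T1 initial contact, T2 contralateral
toe-off, T3 mid-single-support reference, T4 contralateral initial
contact, T5 toe-off, T6 the next initial contact.  Detection needs only
two curves per configuration:

* IMU: the hip flexion-extension curves of both legs (they depend on just
  the pelvis and thigh sensors, so errors do not accumulate down the
  chain);
* optical: the anteroposterior displacement curves of both ankle centres
  (each rigid body has independent precision, so the full foot path is
  trustworthy).

Both curve pairs peak at initial contact and bottom out at toe-off, so one
rule set serves both: T1/T6 at ipsilateral maxima, T5 at the ipsilateral
minimum, T2/T4 at the contralateral minimum/maximum, and T3 where the
contralateral curve crosses the midpoint of its T2-to-T4 excursion.  The
T3 rule is this package's reconstruction (it is used only by the ankle
inversion/eversion range): the crossing sits near mid single support, and
using the *local midpoint* rather than an absolute zero keeps the rule
invariant to constant offsets.  It is isolated in one place in the code.

Numerical choices, each of which matters at 60 Hz where one frame is
nearly 2% of a stride:

* curves are smoothed with a 0.2 s sliding window (Hann by default, flat
  available) before the extremum scan, which suppresses spurious peaks;
* retained extrema must alternate max/min and be at least 0.25 s apart
  (merging keeps the larger prominence; the default separation sits
  comfortably below the toe-off-to-contact gap of a slow stride, while
  `find_extrema`'s own default of 0.4 s suits generic curves);
* each extremum is then *refined*: anchored on a 0.1 s-smoothed copy and
  snapped to the raw-curve extremum within 2 frames.  A symmetric
  smoothing window systematically shifts the extremum of an asymmetric
  peak (gait curves rise and fall at different rates around contact);
  the raw snap removes that bias while the anchor bounds noise jitter;
* events are reported at frame resolution, never sub-frame;
* curves whose excursion is below 2 degrees (or 2 cm) raise a no-events
  error: the method requires visible flexion-extension, and a flat curve
  means it cannot be applied;
* event ordering `T1 < T2 <= T3 < T4 < T5 < T6` is asserted per stride;
  violating strides are flagged invalid and excluded, never reordered.

Over-ground captures include turns and stops; sections to analyse can be
given manually or found automatically as runs where the (unwrapped) pelvis
yaw varies less than 20 degrees over 2 s.

## Gait variables

Twelve variables per stride and side: step length and width (ankle-centre
distances at T1 in the sagittal/frontal plane, read as the anteroposterior
and mediolateral component magnitudes), single support (T2-T4 over the
stride), double support (T1-T2 plus T4-T5), gait speed (stride length over
stride time), and seven kinematic ranges (max minus min of an Euler
component between two events; see `KINEMATIC_VARIABLES` in the source for
the exact windows).  Ranges are computed on the *unsmoothed* tracked
angles: the detection smoothing exists only to stabilise event timing and
would otherwise shave percents off every amplitude.

Stride length is ambiguous on a treadmill, where the T1-to-T6 world
displacement of the ankle is near zero while the *path* is a full stride:
over-ground mode uses the displacement reading, treadmill mode adds the
belt displacement (`belt_speed * stride_time`) back.  Both printed
readings of the definition are thereby honoured in the modality where
each is meaningful.

Stride means use valid strides only; invalid strides are never imputed.
A warning is raised below 23 valid strides, the count usually cited for a
stable gait mean; the reference protocol collects 25.

## Reliability statistics

For test-retest tables (per subject, variable and side):

* `SDpooled = sqrt((sd_test^2 + sd_retest^2)/2)` -- RMS pooling, the
  variance convention; "pooled average of the SD" is ambiguous, so the
  arithmetic mean is available behind `method = "mean"` (the two coincide
  for equal SDs);
* ICC(2,1): two-way random effects, absolute agreement, single
  measurement -- the standard model for a same-rater test-retest design;
  ICC(3,1) behind `model = "3,1"`.  Mean squares come from `stats::aov`;
* `SEM = SDpooled * sqrt(1 - ICC)`,
  `MDC95 = 1.96 * sqrt(2) * SEM`,
  `MDCes95 = MDC95 / SDtest`,
  `MDC95group = MDC95 / sqrt(n)`;
* category summaries (step measures, support percentages, gait speed,
  kinematic ranges) are unweighted means of the MDC95 column, plus the
  mean ICC and MDCes95 over all rows and right/left-averaged MDCs.

Zero between-subject variance makes the ICC undefined and is reported as
an error, not propagated as NaN.  Published per-row MDC95 values cannot
generally be reproduced from printed one-decimal inputs (rounding
propagates: pooling 4.6 and 4.8 with ICC 0.93 gives 3.45 where a table
built from unrounded data prints 3.5), so summary-level checks are the
robust ones.

A bundled reference table (`reference_reliability()`) carries the
published per-variable results of a 33-subject healthy cohort for both
configurations, as a comparison baseline.

## Rigid-body cluster geometry

Each optical cluster of three markers has a maximum orientation error
`Eo = 2 * asin(Ep / Dmin) * 180 / pi` degrees, with `Ep` the camera
system's marker positioning error and `Dmin` the smallest marker-to-marker
distance; the arcsine is kept exact even though linearisation would be
numerically indistinguishable at these scales.  Distinguishability demands
that no two clusters share a sorted distance triple within tolerance
(default 5 mm).  The bundled 15-cluster set (`default_rigid_bodies()`)
ships with `Ep = 0.34` mm.

## The synthetic gait generator

The simulator emits what the hardware would: quaternion streams in
private, randomly-headed Z-up sensor frames (IMU, 60 Hz) or world-frame
rigid transforms (optical, 120 Hz), preceded by a neutral segment for
calibration -- together with ground-truth events and variables.

**Curve family.**  Joint curves are cosines of a *warped* stride phase:
`u(phi)` maps the stance fraction `[0, p]` linearly onto `[0, 0.5]` and
the swing fraction onto `[0.5, 1]`, with `p = 0.5 + double_support/2`.
A cosine in `u` is C1, periodic, and has exactly two extrema, placed
exactly at initial contact and toe-off -- which is what the detection
rules assume of real gait -- while producing the asymmetric single/double
support timing of human walking (40%/20% by default).  A two-harmonic sum
was considered and rejected: no trigonometric polynomial of two harmonics
can place its only extrema at phases 0 and `p != 0.5`.

**Commanded versus derived.**  Step geometry and hip amplitude are coupled
through the legs, so exactly one of `step_length` and `hip_fe_range` is
commanded and the other solved by root finding on the contact-pose forward
kinematics; a constant hip ab/adduction offset is always solved so the
contact-frame ankle spacing equals the commanded step width.  The default
profile commands a hip flexion-extension range of 35 degrees, from which
the leg geometry of a 173.1 cm subject yields a step length near 55-59 cm
at the default knee parameters; speed (120 cm/s) then fixes the stride
time.  The knee curve rises monotonically through stance to its peak at
toe-off: a mid-swing knee peak would put the ankle's anteroposterior
minimum after toe-off (as in real gait) and break the event-locked
extremum placement the optical rules need -- the price is that the knee's
T4-T5 range is a small fraction of its amplitude.  Ranges for the other
five kinematic variables are commanded directly; their curve amplitudes
are scaled so the range over the variable's own event window equals the
command exactly.

**Noise model** (defaults chosen as a realistic magnetometer-free setup):
random per-sensor heading offsets uniform on 0-360 degrees (always on --
they are what the calibration must undo); per-sensor heading drift scaled
by `drift_dps` (0 by default: the workflow recalibrates before each
capture); white orientation noise of 0.1 degrees SD (fused IMU output is
smooth frame-to-frame, so the white component is small); a low-frequency
soft-tissue artefact of 0.2 degrees SD applied to the sensor, not the
bone; and, optically, marker noise of 0.34 mm SD propagated into an
orientation jitter bounded by each cluster's `Eo`.

**Frame-level ground truth.**  Truth event frames are the extremum frames
of the *sampled noise-free* detection curves (within 2 frames of the
rounded continuous event time), and truth support percentages are the
event arithmetic on those frames.  At frame resolution, rounding the
continuous time and taking the sampled extremum disagree systematically on
asymmetric peaks; the sampled-extremum convention is the correct
frame-level answer and converges to the analytic values as the rate grows.

**What the simulator does not model:** ground-reaction forces, muscle
dynamics, foot roll-over geometry, pathological asymmetries, marker
occlusion and mislabelling, and magnetic disturbance transients.  Passing
recovery tests on this generator therefore demonstrates the correctness of
the calibration/tracking/event/variable chain under controlled, realistic
noise -- not clinical validity on real patients.

**Test-retest cohorts** are generated separately and cheaply:
per-subject true values around the profile's variable means with a
between-subject SD, plus independent within-subject measurement error per
session, which gives the reliability module a known SEM to recover.

## Problem sizes and determinism

The shipped test-suite closures use 6-25 simulated strides per modality,
five-to-eight-device captures at 60/120 Hz, reliability cohorts of up to
200 subjects, and fixed seeds throughout; the simulator is bit-identical
under a fixed seed.  Recovery tolerances asserted by the tests: exact
tracked angles (to 1e-6 degrees) without noise; with default noise, at
least 95% of strides with all six events within 2 frames, and 25-stride
mean errors within 1 cm (lengths), 1% (supports), 2 cm/s (speed) and 0.5
degrees (ranges).

## Known limitations

* Heading drift is not corrected inside a capture; long captures degrade.
* The detection rules require visible hip flexion-extension (or ankle
  excursion); gaits without it, or with very large sagittal tremor, are
  outside the method's domain.
* Support percentages inherit frame quantisation: at 60 Hz a single frame
  is 1.7% of a typical stride, which bounds achievable accuracy per
  stride (means over 25 strides average most of it away).
* The anthropometric scaling uses fixed segment proportions; subjects far
  from these proportions bias joint-centre placement in IMU mode.
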