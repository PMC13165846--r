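---
title: "Methods: adaptive complementary filtering and gait parameter estimation in gaitnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive complementary filtering and gait parameter estimation in gaitnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitnet)
```

## Scope and model

gaitnet analyses walking recorded by a seven-node inertial network: one
pelvic node and bilateral thigh, shank and foot nodes, each providing
triaxial gyroscope (rad/s), accelerometer (m/s²) and magnetometer channels
at 200 Hz. The pipeline estimates per-node orientation, detects heel-strike
(HS) and toe-off (TO) events from the foot nodes, reconstructs foot
trajectories with zero-velocity updates (ZUPT), and derives spatiotemporal
parameters and clinical joint/pelvic angles. A synthetic gait simulator
generates ground truth and IMU streams so that every stage can be verified
quantitatively without hardware.

All computations use a right-handed global frame with X mediolateral
(right-positive), Y vertical (up), Z anteroposterior (forward). Orientations
are unit quaternions in Hamilton convention, scalar first, encoding the
sensor-to-global rotation; reference vectors are projected into the sensor
frame through the inverse rotation.

## Orientation: parameter-adaptive nonlinear complementary filter

Rigid-body orientation follows the quaternion kinematic equation
$\dot q = \tfrac12\, q \otimes (0, \boldsymbol\omega)$. Gyroscope
integration alone drifts, so a composite error vector fuses the two vector
observations available at each sample,

$$ \mathbf e = \hat{\mathbf a}_m \times \hat{\mathbf v}_g
   + \hat{\mathbf m}_m \times \hat{\mathbf v}_b, $$

where $\hat{\mathbf a}_m$ and $\hat{\mathbf m}_m$ are the normalized
accelerometer and magnetometer readings and $\hat{\mathbf v}_g$,
$\hat{\mathbf v}_b$ the gravity and magnetic reference directions rotated
into the sensor frame by the current estimate. A PI feedback corrects the
gyro rate:
$\hat{\boldsymbol\omega} = \boldsymbol\omega_{gyro} - \mathbf b
 + K_p \mathbf e + K_i \int \mathbf e \, d\tau$.

Two gains adapt during walking:

* **Proportional gain.** $K_p = K_{p0}\exp(-\alpha(\lVert\mathbf a\rVert - g)^2)$
  with defaults $K_{p0} = 1.8$ and $\alpha = 0.5$ (units
  $1/(\mathrm{m\,s^{-2}})^2$; the squared deviation is taken on the
  acceleration magnitude in m/s², which attenuates the correction below
  2 % of baseline once the magnitude deviates by 3 m/s²). The gain equals
  $K_{p0}$ exactly at quasi-static magnitude and decreases monotonically
  and symmetrically with the deviation.
* **Integral gain.** $K_i$ switches with the detected gait phase of the
  ipsilateral foot: 0.05 during stance-related intervals (stable motion,
  trustworthy gravity reference, strong drift compensation) and 0.005
  during swing. Before event thresholds are initialized the phase is
  "uninitialized" and the stance value is used, because trials begin with
  quiet standing. The pelvic node counts as stance whenever either foot is
  inside a detected foot-flat interval.

Numerical choices: the quaternion update is first order with per-step
renormalization, using the trapezoidal (midpoint) gyro rate so that
oscillatory motion at 200 Hz integrates with third-order per-step error;
the filter predicts with the inertial terms and then corrects against the
vector observations of the same sample, avoiding a one-sample measurement
lag. The integral term is clamped componentwise (default ±1) and only
accumulates while $\lVert\mathbf e\rVert \le 0.2$ (conditional-integration
anti-windup): large alignment transients are handled by the proportional
term, and letting them wind the integral up leaves a residual that drains
on the slow $K_p/K_i \approx 36$ s time scale. The integral is not reset at
phase transitions. The initial orientation is a TRIAD-style closed form
from the mean accelerometer and magnetometer readings of the first static
second. The magnetic reference defaults to a unit vector with 60° downward
inclination in the sagittal plane; errors in this choice affect heading
only, not sagittal angles.

## Calibration

Gyro zero bias is the per-axis mean over a static segment (declared static
when per-axis SD < 0.02 rad/s over ≥ 1 s). Accelerometer calibration uses
the classic six-position method — per-axis scale and bias in closed form
from ±g exposures; cross-axis effects are deliberately left to the
alignment step. Magnetometer hard/soft iron is an algebraic ellipsoid fit
(linear least squares on the general quadric, then symmetric square-root
whitening). Sensor-to-segment alignment defines the anatomical neutral as
all segment frames coincident with the global frame during quiet standing,
so the alignment quaternion is the inverse of the converged static sensor
orientation; the capture counts as converged when the mean orientation of
the first and last quarter of the static window differ by < 0.5°. All
joint angles are therefore zero at calibration by construction.

## Preprocessing

Each channel passes a three-stage cascade: clipping to the sensor
full-scale range (±8 g, ±1000 °/s in SI units), a 5-sample sliding median
(removes isolated outliers), and a 5-sample sliding mean. Windows are 25 ms
at 200 Hz — short enough to preserve heel-strike impulses — and shrink at
the series boundaries so no fabricated samples enter event detection.

## Gait events

HS/TO detection uses a dual-feature rule on each foot node: candidate HS
are local maxima of the global-frame vertical acceleration (gravity
removed) above a peak threshold, candidate TO local minima below a valley
threshold, and each candidate must be confirmed by a zero crossing of the
sagittal foot angular velocity within ±50 ms (downward for HS, upward for
TO). Thresholds are individualized as 0.6 × the mean extremum amplitude of
the first three stable cycles (signed means); bootstrap values of ±2 m/s²
serve until then. A cycle is stable when its HS→TO→HS ordering is
physiological and its duration is within ±20 % of the preceding cycle.
Local extrema use a ±0.25 s neighbourhood with 0.3 s minimum same-type
separation, and non-alternating candidates are dropped keeping the stronger
extremum. The vertical acceleration is the orientation-rotated,
gravity-removed vertical component rather than a raw axis, making detection
robust to mounting variation and, by construction, invariant to uniform
amplitude scaling once thresholds are re-initialized.

## Trajectory and spatiotemporal parameters

Foot acceleration is rotated to the global frame, gravity subtracted, and
integrated trapezoidally. Within each stance, the longest interval with
angular-rate norm < 20 °/s and acceleration magnitude within 0.5 m/s² of
gravity (sustained ≥ 50 ms, with 50 ms guards after HS and before TO) is
the foot-flat anchor. The piecewise-linear velocity ramp through the anchor
midpoints — plus the first and last samples, since recordings start and end
standing — is subtracted before integrating to position, which zeroes
velocity exactly at every anchor and cancels linear drift (hence constant
accelerometer bias) exactly.

Stride length is the displacement between successive same-side initial
contacts projected on the walking axis (the principal horizontal direction
of all contact points); a Euclidean-norm variant is available and the two
agree on straight walking, with the projection never exceeding the norm.
Cadence is $(n_{step}-1)/(t_{end}-t_{start}) \times 60$ counting both feet,
and velocity the net walking-axis displacement over elapsed time. Step
width needs one modelling constant: each foot is dead-reckoned in its own
frame, so the lateral separation of the feet during the initial standing
(default 0.10 m) is unobservable and is added to the measured relative
mediolateral contact displacement.

## Kinematics

Joint rotation is $q_{joint} = q_{prox}^{-1} \otimes q_{dist}$ on aligned
segment orientations, decomposed in a Z–Y–X Euler sequence; under the frame
convention the X (last) angle is the sagittal component, Y transverse and Z
frontal. Clinical signs (hip/knee flexion positive, dorsiflexion positive,
anterior pelvic tilt positive) are applied per joint; with the mediolateral
axis right-positive, hip flexion and dorsiflexion are negative raw X
rotations and knee flexion positive. All three planes are always emitted
even though validation focuses on sagittal and pelvic components, since
Euler cross-talk cannot be excluded. The decomposition is guarded within
0.5° of the ±90° pitch singularity and signals the offending sample rather
than returning ill-defined angles; only the sagittal series is unwrapped.
Per-cycle range of motion (max − min within each stable cycle) and its
trial mean form the scalar used for method-comparison statistics.

## Agreement statistics

The comparison pipeline mirrors a marker-based validation protocol:
reference series are filtered with a fourth-order zero-lag Butterworth
low-pass at 6 Hz (forward–backward passes over a reflection-padded series),
temporal alignment maximizes the normalized cross-correlation of the pelvic
angular-rate-magnitude channel (computed from low-passed pelvic angles on
both sides, avoiding circular dependence on the joint angles being
validated), and both streams are linearly resampled to a common 100 Hz
base. Reported metrics: RMSE, relative RMSE (percent of the reference mean
— meaningful only for positive-mean quantities), Pearson r, Bland–Altman
bias with 95 % limits of agreement (bias ± 1.96 × sample SD of
differences), and ICC(2,1) (two-way random effects, absolute agreement,
single measurement — the conventional choice for method comparison, stated
here as an assumption since agreement indices of this kind are not uniquely
determined). Zero-variance inputs yield `NA` with a classed warning rather
than a number.

## The synthetic gait simulator

`gait_profile()` defaults describe comfortable-speed walking of a healthy
adult on a straight walkway: gait cycle 1.05 s (cadence ≈ 114 steps/min),
stride 1.36 m (≈ 1.30 m/s), duty factor 0.6, 12 cycles bracketed by 2.5 s
of quiet standing, 200 Hz. Hip and knee waveforms are three-harmonic
Fourier series with normal-gait magnitudes (hip ≈ 40° ROM, knee ≈ 60°); the
ankle angle is *derived* from the prescribed shank and foot orientations,
closing the kinematic chain consistently. Pelvic tilt oscillates at twice
the cycle frequency (±2°), pelvic rotation at the cycle frequency (±4°).
A C² quintic envelope ramps the waveforms in and out over one cycle.

Foot trajectories are constructed analytically: forward advance follows a
quintic sigmoid per swing (the leading foot takes a half step first),
vertical motion is a smooth swing bump plus compact C³ polynomial wavelets
at each HS (a few-millimetre heel-compression dip whose acceleration peak
is +12 m/s²) and TO (−12 m/s²). Between those transients the stance foot is
*exactly* stationary, so ZUPT assumptions are verifiable by construction.
Foot sagittal orientation is zero at rest and in mid-stance, with a
plantarflexion excursion around each TO and a dorsiflexion excursion around
each HS — producing exactly the upward/downward angular-velocity zero
crossings the detector requires, at the true event instants. All angular
rates are computed analytically from the same waveforms, so a
finite-difference check of the stored orientations against the stored rates
is an independent consistency test, not a circular one.

The measurement model synthesizes gyro = body rate in the (randomly
misaligned, ~3° RMS) sensor frame + bias + white noise; magnetometer =
rotated global reference + noise; accelerometer = sensor-frame specific
force. Default noise: gyro σ = 0.005 rad/s, accel σ = 0.2 m/s²,
magnetometer σ = 0.01, small constant biases, deterministic per seed.

**A deliberate limitation.** For the pelvis, thigh and shank nodes the
*translational* part of the specific force is scaled by
`linear_accel_scale`, default 0: their accelerometers observe the gravity
reaction plus noise and bias. The reason is structural: a
magnitude-gated complementary filter cannot reject translational
accelerations that are perpendicular to gravity, because they barely change
the magnitude $\lVert\mathbf a\rVert$ while rotating the apparent gravity
direction. With the full rigid-body specific force at the proximal nodes
(`linear_accel_scale = 1`) the thigh/shank orientation error grows to
8–11°, dominated by exactly this rectification. Foot nodes always carry the
full specific force — trajectory reconstruction integrates it, and the
foot's own pattern (large swing accelerations that close the gate, quiet
stance with a truthful gravity direction) is the regime the adaptive gain
is designed for. Consequently, passing recovery tests demonstrate correct
implementation of every stage and the benefit of the adaptive gains under
vector-observation noise, but they do **not** demonstrate robustness of
proximal-segment orientation to translational disturbance; on real data,
errors of a few degrees (as reported for systems of this class) should be
expected rather than the sub-degree recovery seen on the default synthetic
conditions. Soft-tissue artefact can be added as a sinusoidal accelerometer
disturbance (`soft_tissue_amp`), and the full physical measurement model
remains available for stress testing.

## Ablation and verification setup

The adaptive-versus-fixed-gain comparison runs the identical pipeline with
`adaptive = FALSE` (constant $K_p = K_{p0}$, $K_i = K_{i,high}$), holding
the event timeline fixed (ground-truth events label the phases in both
arms) so the gain schedule is the only difference. Across 10 seeds of the
default noisy walk the adaptive filter's mean per-segment orientation RMSE
is consistently about a third of the fixed-gain filter's.

Verification problem sizes, chosen to exercise every stage at desk scale:
one 12-cycle walk (~17.6 s, 3 521 samples × 7 nodes) for zero-noise
recovery, 10 seeds of the same profile for noisy recovery and ablation,
n = 10 000 Gaussian pairs for Bland–Altman coverage. With these sizes the
full test suite runs in well under a minute.

## Known limitations

* Straight, steady, level walking only; no turning, stairs, or pathological
  gait patterns (the waveform library is an extension point).
* Heading depends on a homogeneous magnetic field; indoor disturbance is
  neither simulated nor rejected.
* The proximal-node measurement idealization described above.
* Frontal/transverse joint angles are emitted but not validated.
* Relative RMSE is undefined for zero-mean oscillating variables; it is
  reported only for positive-mean spatiotemporal quantities.
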