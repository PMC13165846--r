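# gaitnet

Gait analysis from a seven-node wearable IMU network — pelvis, bilateral
thighs, shanks and feet — for researchers and engineers building or
validating portable motion-capture pipelines. The package implements the
full processing chain from raw 200 Hz inertial samples to clinical gait
outcomes, plus a synthetic gait simulator that makes every stage testable
without hardware.

## What it computes

* **Orientation** per node via a parameter-adaptive nonlinear complementary
  filter: quaternion gyro integration corrected by a PI feedback on the
  cross-product error `e = â_m × v̂_g + m̂_m × v̂_b` between normalized
  accelerometer/magnetometer readings and the gravity/magnetic references
  projected into the sensor frame. The proportional gain follows
  `Kp = Kp0 · exp(−α(‖a‖ − g)²)` (defaults `Kp0 = 1.8`, `α = 0.5`), so
  accelerometer corrections fade during dynamic phases; the integral gain
  switches with the gait phase (`Ki = 0.05` in stance, `0.005` in swing).
* **Gait events**: heel strike = vertical-acceleration peak above an
  individualized threshold (0.6 × mean amplitude of the first three stable
  cycles) confirmed by a downward sagittal angular-velocity zero crossing
  within ±50 ms; toe off symmetrically with valleys and upward crossings.
* **Foot trajectories and spatiotemporal parameters** via zero-velocity
  updates (ZUPT) anchored in detected foot-flat intervals: stride length,
  step width, cadence `C = (n_step − 1)/(t_end − t_start) × 60`, walking
  velocity.
* **Joint and pelvic angles** from relative segment orientations,
  `q_joint = q_prox⁻¹ ⊗ q_dist`, decomposed in a Z–Y–X Euler sequence with
  clinical sign conventions, plus per-cycle range of motion.
* **Method-comparison statistics** against a reference system: zero-lag
  4th-order Butterworth filtering, cross-correlation temporal alignment,
  100 Hz resampling, then RMSE, relative RMSE, Pearson r, Bland–Altman
  bias/limits of agreement, and ICC(2,1).

Sensor calibration utilities (gyro zero-bias, six-position accelerometer,
ellipsoid magnetometer, neutral-posture sensor-to-segment alignment) and a
three-stage cascaded preprocessing filter (clip → median → mean) round out
the pipeline.

## Worked example

Simulate a default trial (1.05 s gait cycle, 1.36 m stride, 12 cycles,
realistic sensor noise), run the pipeline, and compare against a synthetic
optical-capture-style reference with a known 0.2 s clock offset:

```r
library(gaitnet)

truth  <- generate_gait_truth(gait_profile())
trial  <- synthesize_imu(truth, noise_model(seed = 42))
result <- run_pipeline(trial)
result
#> Gait analysis result
#>   events: 48 (24 left / 24 right)
#> Spatiotemporal gait parameters
#> # A tibble: 1 × 6
#>   stride_length_m step_width_m cadence_spm velocity_ms cycle_time_s n_steps
#>             <dbl>        <dbl>       <dbl>       <dbl>        <dbl>   <int>
#> 1            1.36        0.152        114.        1.29         1.05      24
#>   kinematic variables: hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r,
#>   pelvic_tilt, pelvic_rotation
```

All 48 simulated heel strikes and toe offs are found, and the stride
length (1.36 m), cadence (114 steps/min ↔ the 1.05 s cycle) and walking
velocity (1.29 m/s) match the simulated profile. Agreement against the
noisy reference:

```r
ref <- synthesize_reference(truth, marker_noise_deg = 0.5, lag_s = 0.2,
                            seed = 42)
cmp <- compare_with_reference(result, ref)
cmp[cmp$variable %in% c("knee_l", "pelvic_tilt"),
    c("variable", "rmse", "pearson_r", "bias", "loa_low", "loa_high", "icc")]
#>      variable  rmse pearson_r    bias loa_low loa_high   icc
#> 1      knee_l 0.524     0.999 -0.0732   -1.09    0.943 0.999
#> 2 pelvic_tilt 0.505     0.915 -0.0258   -1.01    0.962 0.911
```

The recovered lag is 0.2 s, RMSEs sit at the injected 0.5° marker-noise
floor, and the small-amplitude pelvic tilt shows the expected lower r/ICC
for the same absolute error. `tidy()`, `glance()` and `autoplot()` methods
give long-format angles, one-row summaries and ggplot2 figures of any
result; `plot_bland_altman()` draws the agreement plot for a comparison
row.

A thin command-line front end ships in `inst/cli/gaitnet.R` with
`simulate`, `run` and `compare` subcommands over trial CSV files.

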