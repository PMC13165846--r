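Package: gaitnet
Title: Multi-Node IMU Gait Analysis with Adaptive Complementary Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for seven-node (pelvis, bilateral thigh, shank
    and foot) inertial measurement unit recordings of walking. Implements
    sensor calibration (gyroscope bias, six-position accelerometer, ellipsoid
    magnetometer), a three-stage cascaded preprocessing filter, a
    parameter-adaptive nonlinear complementary filter for orientation
    estimation, adaptive heel-strike/toe-off detection, zero-velocity-update
    foot trajectory reconstruction, spatiotemporal gait parameters, joint and
    pelvic angle estimation, and method-comparison statistics (RMSE, Pearson
    r, Bland-Altman limits of agreement, ICC). Includes a synthetic gait
    simulator that generates kinematically consistent ground truth and ideal
    or noisy IMU streams so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
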