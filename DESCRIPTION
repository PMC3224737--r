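Package: cervkin
Title: Kinematic Assessment of Fast Cervical Axial Rotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for assessing fast cervical axial head rotation from
    two-receiver 6-DOF orientation recordings: helical-axis kinematics
    (helical angle, 3-D angular speed, finite-helical-axis direction),
    movement segmentation with quintic-spline extrapolation, six kinematic
    variables (peak speed, range of movement, normalized peak amplitude,
    acceleration/deceleration ratio, speed index of deviation from a
    minimum-jerk profile, and conjunct movement via the condition number of
    axis directions), test-retest reliability statistics (ICC, SEM, CV,
    minimal difference), group discrimination by linear discriminant
    analysis with leave-one-out cross-validation and stepwise selection,
    and orthogonal partial least squares (O-PLS) association modelling with
    VIP-based predictor selection. Includes a synthetic-trial generator
    emulating the statistical structure of fast axial rotations in neck-pain
    and control cohorts so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
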