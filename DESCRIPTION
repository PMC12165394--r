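Package: pdgait
Title: Motor-Cognitive Gait Analysis for Parkinson Disease Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline from 3D kinematic trajectories to
    motor-cognitive statistics in Parkinson disease. Segments the Timed Up
    and Go (TUG) test into seven phases from center-of-mass coordinates,
    detects gait events from heel and toe markers relative to the body
    center of mass, extracts spatiotemporal and kinematic walking metrics
    (velocity, stride length, double support, minimum toe clearance,
    Cardan-angle joint range of motion, shoulder symmetry angle), and runs
    a normality-gated correlation, ordinary-least-squares and MANOVA
    battery relating gait to cognitive scores. Includes synthetic
    trajectory and cohort generators with analytic ground truth so every
    pipeline stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
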