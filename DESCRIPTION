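Package: gaitload
Title: Simulated Load Carriage Effects on Lower-Limb Gait Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline for studying how walking speed and carried
    load affect lower-limb joint biomechanics. Generates synthetic gait
    trials (marker trajectories and ground reaction forces) calibrated to
    published kinematic landmarks, scales ground reaction forces
    proportionally to a carried backpack load, computes sagittal-plane
    ankle, knee and hip moments with a planar link-segment Newton-Euler
    inverse-dynamics engine, derives joint power, mechanical work and peak
    outcomes over a speed-by-load grid, and analyses the grid with a
    balanced two-way ANOVA with replicates plus post-hoc multiple
    comparisons. Includes readers and writers for TRC marker and MOT/STO
    force table text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
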