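Package: equigait
Title: Equine Gait Events, Limb Loads and Asymmetry from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring quadruped (equine) locomotion with cannon-bone and
    girth mounted inertial measurement units sampled at 120 Hz. Reads per-sensor CSV
    time series, estimates the gait-cycle period from the oscillating pitch angle,
    segments strides from sagittal-plane angular velocity, detects hoof-on and
    hoof-off events as tri-axial acceleration-magnitude peaks, and derives stride
    frequency, stance and swing durations, duty factor, peak impact limb load (PILL),
    and longitudinal/lateral limb-load asymmetry indices. Includes a synthetic
    five-sensor gait simulator (walk, trot, left/right-lead canter) with per-stride
    ground truth, cohort-level repeated-measures statistics with effect sizes, a
    sensor-agreement (Bland-Altman) analysis, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
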