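Package: skitrax
Title: Micro-Sensor Performance and Sub-Technique Analysis for Cross-Country Skiing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for in-field analysis of classical cross-country skiing races
    from body-worn micro-sensors. Reads 10 Hz GNSS tracks and 100 Hz inertial
    measurement unit (IMU) streams, derives speed and cumulative distance,
    segments a race course into uphill, flat and downhill terrain using a
    4 m elevation-difference rule, resamples laps onto a common distance grid
    to compare skiers and groups (relative speed difference, accumulated time
    difference, per-terrain time loss), classifies classical sub-techniques
    (double poling, kick double poling, diagonal stride, other) from
    low-pass-filtered accelerometer and gyroscope z-components with a
    sliding-window k-nearest-neighbour classifier, and summarises sub-technique
    usage per distance and per time across speed bins. A seeded race simulator
    generates courses, speed profiles, GNSS tracks and technique-specific
    cyclic IMU signals with known ground truth so every pipeline stage can be
    validated without athlete data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
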