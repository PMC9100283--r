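Package: skelmerge
Title: Multi-Sensor Markerless Skeleton Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Merges noisy 3D human skeleton streams captured by multiple RGB-D
    sensors into a single accurate skeleton track. Provides sphere-trajectory
    extrinsic calibration (RANSAC sphere fitting and SVD rigid registration),
    marker-plate global-frame calibration, left/right misorientation correction,
    density-based (DBSCAN) joint-candidate merging with reference and
    previous-position auxiliary candidates, and per-joint Kalman tracking, along
    with a synthetic multi-sensor gesture simulator and evaluation tools
    (per-region joint position error, searching-area sweeps, sensor-subset
    sweeps, and fusion-variant comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
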