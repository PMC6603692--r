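Package: gaitstab
Title: Stability of Running Gait Patterns from Wearable IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Determines how many running sessions are needed to establish a
    stable, subject-specific gait pattern from a single wearable inertial
    measurement unit (IMU), across level, uphill, downhill and mixed elevation
    conditions. Implements GPS-based run trimming, speed gating and 100 m
    elevation windowing; univariate and multivariate normal density models
    with a 95%-coverage density threshold (epsilon) and similarity scoring;
    a quantile-change stability criterion over accumulating runs with
    leave-one-out train/test enumeration; and a crossover condition analysis
    correlating out-of-contour counts across elevation conditions. Includes a
    seeded synthetic cohort generator emulating multi-runner, multi-run IMU
    and GPS streams so the whole pipeline is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
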