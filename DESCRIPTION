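Package: pairguard
Title: Dyadic Proximity and Mate-Guarding Analysis from GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify mutual mate guarding in pair-living birds from
    high-frequency GPS telemetry. Implements plausibility filtering of raw fix
    streams (distance-from-capture, implied-speed and single-outlier rules),
    nearest-in-time pairing of asynchronous dyad fixes, a three-rule dynamic
    threshold classification of when two individuals are together, detection and
    attribution of separation movements, nest-attendance classification, a
    random non-breeding pair null model, clutch-initiation date estimation from
    nest evidence, and binomial/beta-binomial/Gaussian mixed models with random
    slopes over breeding day. A correlated-random-walk simulator of paired
    tracks with known ground truth supports end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    glmmTMB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
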