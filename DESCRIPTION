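Package: canopyclust
Title: Crop Canopy Localization from Ultrasonic Range Scans by Fuzzy ISODATA Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts sensor-to-canopy and sensor-to-ground distances from
    1-D ultrasonic range scans recorded over crop plants, as used for sprayer
    boom height control. Implements fuzzy c-means clustering with ISODATA-style
    split and merge adjustment of the cluster count, a partition-entropy
    validity index, canopy/ground extraction with a ground-plausibility check,
    comparison baselines (k-means, mean, median), and a seeded synthetic scan
    simulator that emulates multi-level leaf/ground echo structure, echo
    dropout, and the dependence of sample count on sensor speed. Includes a
    command-line interface for clustering, simulation, and method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
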