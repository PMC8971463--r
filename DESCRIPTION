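Package: wristhar
Title: Child Activity Recognition from Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("wristhar", "developers", email = "wristhar@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for human activity recognition (HAR)
    from wrist-worn inertial measurement units (IMU) in children: synthetic
    multi-subject cohort simulation with a 40-activity registry, overlapping
    sliding-window segmentation with window-end label resolution,
    time- and frequency-domain feature extraction, per-activity one-vs-rest
    gradient-boosted classification under subject-independent threefold
    cross-validation, weighted-AUC summaries, and quadratic window-size
    effect analysis with an AUC effect-size relevance rule.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
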