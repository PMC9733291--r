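Package: timeactivity
Title: Automated Classification of Time-Activity-Location Patterns from
    Personal Monitor Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies per-minute time-activity-location patterns
    (home/work/other crossed with indoor/outdoor, sleep, and five
    transport modes) from multichannel personal-monitor traces (GPS,
    accelerometer, microphone, docking state and optional pollutant
    channels). Implements a six-step pipeline: night-time dock-based home
    identification with an elliptical buffer zone; time-scaled-distance
    local convex hulls to separate static clusters from directional
    movement; visit metrics and home/work/other role assignment; rule
    based GPS gap interpolation and indoor/outdoor separation; sleep
    detection from noise, movement and coarse-particle dynamics; and
    journey segmentation (penalized-contrast dynamic programming) with
    random-forest transport-mode classification, three-step variable
    selection and grouped 10-fold cross-validation. Includes a
    ground-truthed synthetic cohort simulator and confusion-matrix /
    time-budget evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
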