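Package: skelmatch
Title: Single-Exemplar Skeletal Activity Recognition via Bone-Angle Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes human activities from skeletal joint streams (Kinect-v1
    style, 20 named joints) by comparing bone directions of an observation
    against a single key sample per activity. Implements activity-specific
    relevant-joint subsets (extremity-only, extremity-plus-trunk, whole-body
    variants), per-activity minimum limits of prediction for easily detected
    "sink" activities with interval-based calibration of those limits, a seeded
    parametric generator of labeled synthetic skeleton motion, and an
    evaluation harness producing success/victory/rate tables and confusion
    matrices for paired strategy comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
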