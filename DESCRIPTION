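Package: fallseg
Title: Event-Centered Data Segmentation for Accelerometer-Based Fall
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A testing environment for studying how event-centered data
    segmentation affects accelerometer-based fall detection.  Implements
    acceleration vector magnitude (AVM) computation, record-level quality
    control, threshold-plus-quiet-period detection of potential fall
    events with per-dataset threshold calibration, a parameterised
    three-window (pre-impact / impact / post-impact) segmentation model,
    eight per-segment magnitude features, and cross-validated support
    vector machine evaluation over the full grid of window
    configurations.  A synthetic tri-axial accelerometry generator
    emulates fall and activity-of-daily-living (ADL) records so the whole
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
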