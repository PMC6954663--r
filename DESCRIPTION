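Package: shapeEvents
Title: Detection of Structural Transition Events in Cotranscriptional
    SHAPE-Seq Reactivity Matrices
Version: 0.1.0
Authors@R:
    person("shapeEvents", "Maintainers", email = "maintainers@shapeevents.dev",
           role = c("aut", "cre"))
Description: Automated detection of RNA structural transition events in
    cotranscriptional SHAPE-Seq reactivity matrices (transcript lengths by
    nucleotide positions, rho-normalized).  Swing events (rapid reactivity
    changes over few transcript lengths) are detected with a proportional-
    integral feedback-control inspired scheme with seven independently
    tunable thresholds; ramp events (gradual changes over many lengths) are
    detected with sliding-window linear regression.  Includes elbow-based
    automated threshold selection, replicate consensus calling, concurrent
    event grouping, lagged up-then-down pattern mining, a ternary-model
    reactivity simulator with an RNA polymerase footprint for ground-truth
    benchmarking, and threshold sensitivity-analysis cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
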