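Package: arcverify
Title: Automated Delivery Verification for Volumetric-Modulated Arc Therapy
Version: 0.9.0
Authors@R:
    person("arcverify", "maintainers", email = "arcverify@example.org",
           role = c("aut", "cre"))
Description: Tools for daily quality assurance of volumetric-modulated arc
    therapy (VMAT) deliveries. Compares machine-reported delivery snapshots
    against planned arc control points by linear interpolation on cumulative
    monitor units, computes signed multileaf-collimator (MLC), gantry and jaw
    position errors with jaw-blocked-leaf exclusion, aggregates them into
    percent-within-tolerance, per-leaf RMS and histogram summaries, renders
    per-fraction and historical trend reports, and evaluates configurable
    alert rules. A synthetic plan generator and delivery simulator with a
    speed-proportional latency error model replace the clinical record-and-
    verify database so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
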