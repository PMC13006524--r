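Package: larvaforce
Title: Segmentation and Analysis of Larval Counteracting Force Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how Drosophila melanogaster larvae
    counteract external mechanical pressure in a tilted-cleft force assay.
    Segments force-sensor telemetry into peristaltic force waves using
    prominence-based peak detection with wave-period boundary rules, computes
    per-wave metrics (peak-to-peak force change, per-bout force change,
    amplitude, duration, inter-wave delay, and elastic work), rescales metric
    series across consecutive waves, quantifies behaviour-force coupling with
    point-biserial correlation, and simulates the closed-loop operant training
    protocol in which each peristaltic wave triggers a commanded force change.
    Includes a seeded synthetic virtual-larva trial generator with ground-truth
    waves for validating the measurement pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
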