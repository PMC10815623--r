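Package: strbaseline
Title: Analytical Thresholds for STR Electropherograms from Negative-Control Baseline Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving analytical thresholds (ATs) for short tandem
    repeat (STR) capillary-electrophoresis data from the baseline signals of
    amplification negative controls. Parses GeneMapper-style sizing-table
    exports, applies the standard signal-cleaning cascade (read-region,
    internal-lane-standard proximity, locus screening, pull-up removal),
    summarises per-dye baseline noise including a lognormal height model,
    and computes five published negative-signal threshold estimators
    alongside a static empirical threshold. Threshold choices are scored
    against a reference genotype by allele-dropout and non-allelic-peak
    counting, 1-200 RFU sweeps, ROC analysis and total error rate. A
    synthetic-data module generates negative-control and low-template
    positive profiles so the whole pipeline is testable without instrument
    data, and a command-line entry point reproduces the NegaProcess-style
    baseline report (spreadsheets plus a height-distribution figure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
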