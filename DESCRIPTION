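Package: pkgfluct
Title: Percent Time in Bradykinesia and Dyskinesia and Motor-Fluctuation
    Classification from Wrist-Sensor Epoch Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-epoch bradykinesia and dyskinesia scores
    produced by wrist-worn movement loggers in Parkinson's disease, such as
    the Parkinson's KinetiGraph (PKG). Computes the median-score family
    (median and active median bradykinesia score, median and adjusted median
    dyskinesia score), percent time in bradykinesia (PTB) and in dyskinesia
    (PTD) against published target ranges, calibrates bradykinesia scores to
    a six-level UPDRS-III-equivalent severity scale, estimates the first-dose
    levodopa response and wearing-off from dose-reminder events, and
    classifies subjects into six fluctuator categories. Includes a synthetic
    cohort simulator with known ground truth for validating every pipeline
    stage, cohort-level treatment-change summaries, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
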