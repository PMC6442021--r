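Package: mamsoc
Title: Operating Characteristics of Multi-Arm Multi-Stage Trial Designs
    with Efficacy Stopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design evaluation for multi-arm multi-stage (MAMS) randomised
    trials with time-to-event outcomes that assess lack-of-benefit on an
    intermediate outcome at interim analyses and permit early stopping for
    overwhelming efficacy on the definitive outcome.  Constructs stagewise
    lack-of-benefit and efficacy boundaries (Haybittle-Peto, O'Brien-Fleming
    type alpha-spending, or custom rules), builds the joint correlation
    structure of all stagewise test statistics induced by the shared control
    arm and the information-time structure, and computes pairwise and
    familywise type I error rates (actual and non-binding maxima) and
    per-pair, any-pair and all-pair power, both by Dunnett-type
    multivariate-normal integration and by Monte-Carlo simulation.  Includes
    a search procedure that adjusts the final-stage significance level to
    strongly control the familywise error rate at a prespecified level and
    reports the event-count consequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
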