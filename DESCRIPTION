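Package: dualchange
Title: Dual-Factor Reliable Change Analysis for Well-Being and Distress Outcomes
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pre-post evaluation of mental-health interventions under the
    dual-factor model, in which mental well-being and psychological distress
    are distinct, negatively related dimensions. Scores the MHC-SF, SWLS,
    DASS-21 and BRS instruments with configurable severity cutoffs, computes
    Jacobson-Truax style reliable change indices per participant and outcome,
    classifies within-individual differential change patterns (both /
    well-being only / distress only / none), and runs the group-level
    inference battery: repeated-measures and two-group MANOVA via Hotelling's
    T2 with Wilks lambda and partial eta squared, baseline-stratified Welch t
    tests with Cohen's d, Mann-Whitney robustness checks and Cronbach's
    alpha. Ships a synthetic cohort generator with configurable pre-post and
    cross-outcome correlation structure so the full pipeline is testable
    without participant-level data, plus a command-line driver.
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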