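Package: triagesim
Title: Simulation of Scarce-Resource Triage Protocols Under Ventilator Shortage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates crisis-standards-of-care triage: declarative rule sets
    for scarce-resource-allocation (SRA) protocols (exclusion screening, SOFA
    and multi-principle priority scoring, tie-break chains with first-come
    first-served and seeded lotteries) applied to critically ill patient
    cohorts competing for a limited number of ventilators. Builds
    patients-by-protocols allocation matrices, quantifies between-protocol
    concordance, estimates per-patient allocation probability by Monte Carlo
    under randomized tie-breaks, and calibrates under-specified protocol
    parameters by exhaustive grid search against a target allocation column.
    Ships six calibrated protocol configurations, a nine-patient demonstration
    cohort, a synthetic cohort generator, and a SOFA (Sequential Organ Failure
    Assessment) calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
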