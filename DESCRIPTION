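Package: manusplit
Title: Design, Scoring and Analysis of Split-Manuscript Reporting Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for split-manuscript randomized trials in which the six
    methods-section domains of a manuscript (trial design, randomization,
    blinding, participants, interventions, outcomes) are randomized within
    each participant, three to a structured writing-aid condition and three
    to usual writing. Provides permuted-block randomization over the twenty
    3-of-6 allocation patterns, cluster-crossover sample-size calculation
    with the design-effect inflation factor 1 + (m-1)*rho - m*rho', weighted
    keyword-rubric scoring of completeness of reporting standardized to a
    0-10 scale with dual-rater consensus adjudication, the paired
    split-unit estimator of the intervention effect (the exact
    generalized-least-squares solution of the participant + participant-by-
    condition mixed model in the balanced case), ANOVA-type variance-component
    estimation, per-domain Student t-tests, a paired comparison against
    published reports, and a synthetic-trial generator realizing the assumed
    correlation structure for power, type-I-error and weight-sensitivity
    simulation.
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
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
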