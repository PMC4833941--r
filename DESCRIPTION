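Package: crtpathways
Title: Pathways and Mediation Analysis for Pair-Matched Cluster-Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how a community-level intervention achieves
    its effect in a pair-matched cluster-randomised trial (CRT) of a binary
    outcome, built around the pathways analysis of community-mobilisation
    trials for intimate partner violence (IPV) prevention. Provides a
    declarative engine that turns item-level survey responses into composite
    binary indicators with correct eligibility denominators; enumeration-area
    (EA) level aggregation of community norms; a pair-matched cluster-level
    intention-to-treat risk-ratio estimator based on observed/expected ratio
    residuals from an individual-level logistic model; modified Poisson
    regression (log-link Poisson on a binary outcome) fitted by iteratively
    reweighted least squares with cluster-robust sandwich variance; and a
    mediation-by-attenuation ledger quantifying the share of the intervention
    effect explained by community-, relationship- and individual-level
    factors. A synthetic-data module generates pair-matched CRT survey waves
    with a known mediated fraction so every stage can be validated against a
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
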