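Package: mamsio
Title: Operating Characteristics of Multi-Arm Multi-Stage Trials with
    Intermediate Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design evaluation for multi-arm multi-stage (MAMS) clinical
    trials in which interim analyses use an intermediate outcome (such as
    failure-free survival) and the final analysis uses a definitive outcome
    (such as overall survival). Computes pairwise and familywise type I
    error rates analytically via multivariate-normal orthant probabilities
    and by Monte-Carlo simulation of the correlated stagewise z-statistics,
    finds the final-stage significance level that controls either error
    rate in the strong sense, and approximates stagewise control-arm event
    requirements. Includes a command-line interface for design reports,
    effect-scenario sweeps and significance-level searches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
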