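Package: rdsforest
Title: Respondent-Driven Sampling Estimators, Diagnostics and Recruitment
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing respondent-driven sampling (RDS) surveys of
    hidden populations: recruitment-forest construction with seed-productivity
    cuts, crude and network-weighted prevalence estimators
    (Salganik-Heckathorn RDS-I, Volz-Heckathorn RDS-II and a
    successive-sampling RDS-SS estimator) with grouped chain-bootstrap
    confidence intervals, Markov-chain recruitment diagnostics (convergence
    and bottleneck series, homophily indices, waves to equilibrium),
    seed-exclusion sensitivity analysis, a seed-tree subsampling comparison
    of estimators, and a group-structured network plus coupon-recruitment
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
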