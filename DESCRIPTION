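Package: lsmeval
Title: Operational Evaluation of Drone- and AI-Assisted Larval Source Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating larval source management (LSM) field
    operations against conventional practice: labour-intensity indicators
    (total person-days per unit area), larvicide-use efficiency (sites
    treated per pack), drone versus manual waterbody detection ratios, a
    labour-cost-margin and drone break-even economic model, exact
    small-sample Mann-Whitney rank-sum and Pearson chi-square inference,
    a gradient-boosted categorical classifier for larval habitat risk,
    CDC light-trap catch summarisation, and a seeded synthetic-data
    generator so every stage of the pipeline is testable without field
    data. Ships the printed operational tables of a Ghanaian
    cluster-comparison study as plain-text fixtures together with a
    one-shot harness that recomputes every desk-reproducible statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
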