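Package: lynchcea
Title: Cost-Effectiveness Modelling of Reflex Testing for Lynch Syndrome in
    Endometrial Cancer
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic model of reflex tumour-based testing strategies
    to identify Lynch syndrome in women newly diagnosed with endometrial
    cancer, with cascade predictive testing of relatives. A diagnostic
    decision tree is coupled to a monthly-cycle Markov cohort model of
    lifetime colorectal cancer outcomes under colonoscopic surveillance.
    Includes a full cost-effectiveness engine (ICERs, dominance and extended
    dominance, net monetary benefit, acceptability curves), probabilistic and
    one-way sensitivity analysis, age-heterogeneity and age-threshold policy
    analysis, bivariate meta-analysis of diagnostic accuracy, and synthetic
    data generators for every tabulated input.
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
    withr
Config/testthat/edition: 3
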