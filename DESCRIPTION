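Package: netcea
Title: Cost-Effectiveness Modelling of Imaging Strategies for Neuroendocrine Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness modelling of diagnostic
    imaging strategies (68Ga-DOTA-TATE PET/CT, 111In-pentetreotide SPECT/CT,
    and CT alone) for the workup of suspected neuroendocrine tumors. A
    diagnostic decision tree maps prevalence and test performance to true/false
    positive and negative outcomes; each outcome enters a lifetime Markov
    cohort model with annual cycles, background mortality from a life table,
    and discounted cost and quality-adjusted life-year accumulation. The
    package computes incremental cost-effectiveness ratios with dominance and
    the efficiency frontier, net monetary benefit, one-way deterministic
    sensitivity analysis (tornado), and probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves. An individual-level
    microsimulation oracle and synthetic life-table/configuration generators
    make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
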