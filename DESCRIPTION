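Package: vitdcea
Title: Cost-Utility Analysis of Vitamin D Supplementation Against
    Pediatric Acute Respiratory Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model of daily vitamin D
    supplementation for preventing acute respiratory infections (ARI) in
    school-age children over a six-month horizon. Provides a two-strategy
    decision tree with four terminal health states, base-case roll-back of
    expected costs and quality-adjusted life-years, incremental analysis
    with dominance and ICER classification, net monetary benefit, one-way
    deterministic sensitivity analysis (tornado), and second-order Monte
    Carlo probabilistic sensitivity analysis with cost-effectiveness plane,
    acceptability curves and frontier. Parameter uncertainty is described
    by beta, gamma and lognormal distributions fitted by the method of
    moments from published means and standard deviations. All results are
    returned as tibbles; fitted analyses have tidy(), glance() and
    autoplot() methods.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
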