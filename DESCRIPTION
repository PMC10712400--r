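Package: bmimarkov
Title: Markov-Chain Modelling of Long-Term Adult Weight-Status Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates survey-weighted BMI-category transition matrices from
    paired (recalled past, current) weight records, projects category
    prevalences forward by decades with a discrete-time Markov chain,
    characterizes the stationary distribution, and quantifies uncertainty by
    bootstrap resampling of individuals. Ships a seeded synthetic-cohort
    generator that emulates the demographic and weight-change structure of a
    nationally representative adult survey cohort, so the whole pipeline is
    testable without any external data download. Includes descriptive summary
    tables with hypothesis tests, weight-change histograms, stratified
    (sex, race) runs, and a reproducible run-report writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
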