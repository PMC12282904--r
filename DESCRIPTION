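Package: htnscreen
Title: Markov Cohort Cost-Effectiveness Modelling of Hypertension Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime Markov cohort model for the economic evaluation of
    population blood-pressure screening strategies. Ten mutually exclusive
    health states track hypertension diagnosis and treatment and downstream
    cardiovascular events (myocardial infarction, stable and unstable angina,
    stroke, transient ischaemic attack); annual cycles accrue discounted costs
    (PPP international dollars) and quality-adjusted life years. The package
    provides a validated base-case parameter set, a seedable synthetic
    generator for the age-indexed incidence, treatment-uptake and mortality
    schedules, screening-strategy rosters (start age by interval), a cohort
    engine with an independent microsimulation oracle, incremental
    cost-effectiveness analysis with dominance classification and the
    efficiency frontier, net monetary benefit, one-way deterministic
    sensitivity analysis (tornado data) and probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
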