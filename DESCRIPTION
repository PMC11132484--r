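Package: cvdspread
Title: Agent-Based Simulation of Social Spread of Cardiovascular Risk Behaviours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: City-scale agent-based simulation of how four behavioural risk
    factors for cardiovascular disease (smoking, alcohol consumption, poor
    diet and physical inactivity) spread through marriage, household,
    friendship and workplace networks, and of the resulting CVD incidence.
    Provides synthetic-population generation from CSV-configured demographic
    distributions, a multi-behaviour linear-threshold influence model with
    three adoption levels per behaviour, a simplified QRISK3-style ten-year
    risk score with behaviour-level multipliers, annual-step simulation with
    incidence reporting per 1,000 person-years by age group and sex,
    workplace-intervention experiments, and calibration of influence
    strengths by random-restart hill climbing against observed incidence
    rates.
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
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
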