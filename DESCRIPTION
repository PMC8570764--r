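Package: hefsim
Title: Microsimulation of Diabetes Care and Health Equity Fund Coverage in
    Cambodia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov microsimulation of the diabetes care
    cascade (screening, diagnosis, drug therapy, complications, mortality)
    for a Cambodian cohort, used to evaluate benefit packages of the Health
    Equity Funds (HEF), Cambodia's fee-exemption scheme for the poor.
    Generates synthetic populations with gamma-distributed household income,
    simulates 45 annual cycles under alternative coverage strategies with
    common random numbers, and aggregates person-year ledgers into societal
    costs, disability-adjusted life-years, catastrophic health expenditure,
    impoverishment, and incremental cost-effectiveness ratios. Includes
    probabilistic sensitivity analysis over the parameter distributions and a
    population bootstrap.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
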