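Package: colonmsce
Title: Two-Pathway Multistage Stochastic Model of Colon Cancer Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic multistage clonal-expansion modelling of human colon
    carcinogenesis with two competing molecular pathways: chromosomal
    instability (CIN, four stages) and microsatellite instability (MSI, five
    stages).  Provides the expected-number solutions (closed form and ODE),
    exact forward simulation of the birth-death-mutation branching process,
    tumour-onset probabilities and the Poisson observation model for
    age-grouped incidence tables, and a generalized-Bayesian fitting procedure
    (multi-level Gibbs sampling with data augmentation by weighted bootstrap).
    Ships the SEER colon cancer incidence table used as the reference data set
    together with simulation, fitting, prediction and reporting tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
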