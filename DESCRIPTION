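Package: cvdsim
Title: Compartmental Simulation of Cardiovascular Risk-Reduction Policies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale system-dynamics model of cardiovascular risk in the
    United States population, 1990-2040. Advances age/sex/disease-status
    population stocks and categorical risk-factor prevalences by quarter-year,
    converts prevalences into event and death hazards through multiplicative
    relative risks, and evaluates 50 policy intervention levers grouped into
    six care/air/lifestyle clusters. Computes deaths and years of potential
    life lost per thousand adults and three discounted per-adult cost
    accounts, compares intervention scenarios against a status-quo base case
    over 2012-2020 and 2012-2040 windows, and quantifies uncertainty with a
    paired Monte Carlo probabilistic sensitivity analysis over 89 uniformly
    distributed intervention effect-size parameters. Ships a synthetic,
    calibrated parameter bundle plus tools to rebuild or recalibrate it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
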