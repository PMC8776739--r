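Package: compsel
Title: Competition-Selection Modelling of Phytoplankton Under Toxic Metal Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits acute Weibull dose-response curves for toxicant growth
    inhibition in microalgal strains, derives standardized inhibition
    coefficients and effective concentrations (ECx), and projects the outcome
    of inter-species competition with intraspecific strain selection under a
    deterministic exponential-growth model with semicontinuous dilution.
    Includes analysis of observed co-culture time series (interval growth
    rates, relative inhibition, species relative biomass, frequentist
    comparisons) and a seeded synthetic-data generator emulating
    dose-response plates and microscopy-counted co-culture experiments, so
    the full pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
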