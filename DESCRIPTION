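Package: tcmfit
Title: Time-Concentration-Mortality Models for Insect Pathogen Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the time-concentration-mortality (TCM) model to replicated
    cohort bioassays of entomopathogenic fungi and other stage-structured
    insect pathology experiments. Daily cohort counts are reduced to
    conditional (interval) form and modelled with a complementary log-log
    binomial likelihood in which mortality depends jointly on log10 conidial
    dose and per-day time effects. Includes Abbott's control-mortality
    correction, Hosmer-Lemeshow goodness-of-fit testing, inversion of the
    fitted model to lethal concentrations (LC50) and lethal times
    (LT50/LT90), a synthetic bioassay generator for validation, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    multcomp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
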