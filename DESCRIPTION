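Package: abasignal
Title: Dynamic Modeling of ABA-Dependent RD29A Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary-differential-equation model of the abscisic
    acid (ABA) signaling pathway driving expression of the Arabidopsis drought
    marker gene RD29A through the core components PYR, PP2C, SnRK2, ABF,
    DREB2A, MAP3K and the 26S proteasome, with ABRE/DRE promoter-occupancy
    logic and negative feedback through ABRE-driven PP2C expression. Provides
    the two-phase simulation protocol (equilibration then ABA step), in-silico
    gene knockouts, feedback-loop ablation, dose-response scans, local
    sensitivity analysis, bounded grid-search calibration of the three
    undetermined expression parameters against luminescence time courses, a
    synthetic RD29A::LUC luminescence generator, and SBML export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
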