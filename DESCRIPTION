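Package: cotyledonsim
Title: Seven-Compartment Simulation of the Ex Vivo Cotyledon Perfusion Assay
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of drug transfer in the dually perfused
    human placental cotyledon. Implements a seven-compartment ordinary
    differential equation model of the ex vivo perfusion assay (maternal and
    fetal reservoirs, intervillous and intravillous perfusate, interstitial
    spaces and trophoblasts), tissue-to-perfusate partition coefficients
    computed from tissue composition (including the Rodgers-Rowland method),
    albumin-ratio scaling of the fraction unbound, multi-start estimation of
    placental transfer parameters from reservoir concentration-time data,
    local sensitivity analysis over the trophoblast partition coefficient,
    a synthetic-campaign generator for method validation, and export of
    fitted parameters for coupling to maternal-fetal physiologically based
    pharmacokinetic (PBPK) models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
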