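Package: nanoband
Title: Bayesian Network Control Banding for Nanomaterial Occupational Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A discrete Bayesian-network engine for occupational risk
    characterization of engineered nanomaterials. Provides network
    definition and validation with width-growing concentration bins,
    exact posterior inference by variable elimination (with a
    joint-enumeration oracle), expectation-maximization parameter
    learning from case tables with missing cells, experience-weighted
    sequential Dirichlet updating, and the four-step risk pipeline:
    occupational exposure limit derivation from a NOAEL or LOAEL,
    exposure posteriors over airborne-concentration bins, hazard-quotient
    forecasts with 90 percent credible intervals, and control-band
    classification with heat-map coordinates. Ships parameterized default
    networks for carbon nanotubes, nano-silver and nano-titania, and a
    synthetic case-table generator with missing-completely-at-random
    masking for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
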