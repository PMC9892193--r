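Package: nbalance
Title: Nitrogen-Balance Quantification of Biofilm Biomass and
    Biomass-Specific Rates in Bioelectrochemical Reactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Operando estimation of total, planktonic and biofilm biomass in
    continuously operated biofilm electrochemical reactors (e.g. microbial
    electrosynthesis of carboxylates from CO2) from routine total-nitrogen
    and optical-density measurements, using an elemental nitrogen balance.
    Derives biomass-specific production rates (q-values) and specific growth
    rates (mu) on a carbon-mole basis, Faradaic efficiency from integrated
    cathodic charge, and the standard reactor key performance indicators
    (titers, volumetric rates, electrode-normalized rates and current
    densities, biofilm space occupancy). Includes a seeded ODE simulator of
    a continuously fed biofilm electrosynthesis reactor and its observation
    process, so every pipeline stage can be validated against known ground
    truth without laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
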