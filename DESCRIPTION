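Package: fermgas
Title: Headspace Gas Balance and Accounting for Dark-Fermentation Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying biological hydrogen and carbon dioxide
    production in sparged batch bioreactors. Implements the nitrogen-carrier
    headspace mass-balance model (forward simulation with setpoint control of
    the outlet hydrogen fraction, and inverse reconstruction of biological gas
    production rates from off-gas records), dissolved carbon dioxide
    speciation from headspace partial pressure and pH, and the fermentation
    accounting layer used in dark-fermentation studies of Thermotoga
    maritima: carbon recoveries, molar yields, volumetric and specific rates
    with logarithmic-mean biomass, cell yield on thiosulfate by restricted
    least squares, sulfur budgets and hydrogen detoxification stoichiometry.
    A synthetic batch-run generator with the same stoichiometric structure
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
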