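Package: tundraflux
Title: Automated-Chamber Methane Flux Processing for Arctic Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for automated-chamber greenhouse
    gas flux campaigns on well-drained Arctic tundra. Generates seeded
    synthetic campaigns with known ground-truth methane fluxes, estimates
    fluxes from closure concentration traces by linear or saturating
    exponential fits with unit conversion and fit selection, applies
    physically motivated quality control (chamber pressure consistency,
    night-time low-turbulence filtering), aggregates hourly fluxes to daily
    sums and diel composites with gap filling, quantifies daytime-only
    sampling bias, and attributes flux variation to abiotic and biotic
    drivers via random-forest importance, added variance from ecosystem
    respiration, and transfer-entropy lag detection, plus group-comparison
    statistics for manual-chamber surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    minpack.lm,
    randomForest,
    igraph,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
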