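Package: macroflux
Title: Static-Chamber Methane Flux Estimation and Temporal Analysis for
    Emergent Macrophyte Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns closed-chamber greenhouse-gas analyser logs into
    plant-mediated methane flux estimates and analyses their temporal
    structure.  Implements sliding-window regression with best-r2 window
    selection, ideal-gas conversion of concentration slopes to areal fluxes,
    screening of ebullition (bubble) events, Henry's-law diffusive flux
    estimation, diel time-class binning with intra-class correlation,
    daily-mean regressions, and all-subsets AIC model averaging of Gamma
    log-link generalized linear models.  Includes a synthetic-data generator
    emulating a two-lake, two-species seasonal chamber campaign with known
    ground truth, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
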