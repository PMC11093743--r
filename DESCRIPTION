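Package: percebe
Title: Wave Climate and the Morphometric Quality of Stalked Barnacle Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a changing nearshore wave climate to the morphometry and
    market quality of the stalked barnacle (Pollicipes pollicipes). Transforms
    offshore sea states to inshore maximum wave heights and orbital currents
    by linear wave theory shoaling, decomposes daily orbital-current series
    into seasonal and long-term components with penalized regression splines,
    classifies individuals against the sigmoidal Parada quality limit and
    computes the high quality fraction (HQF), derives topographic exposure
    metrics (relative wave incidence angle, nearshore slope) from coastline
    and bathymetry data, quantifies site-level coupling between winter orbital
    currents and morphometry with exhaustive AICc-ranked model selection, and
    analyses the Gompertz quality-morphometry law in the length-width plane.
    Includes a seeded synthetic-data generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
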