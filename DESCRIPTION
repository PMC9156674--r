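Package: firemosaic
Title: Fire-Regime Reconstruction and Callitris Demography in Savanna Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing savanna fire regimes from seasonal
    surface-reflectance composites (differenced normalized burn ratio mapping,
    time-since-fire grids, long-unburnt patch mosaics, pre/post-intervention
    regime statistics) and for analysing the demography of the fire-sensitive
    conifer Callitris intratropica (size-class structure, annualized survival,
    dendrochronological establishment dating with pith and sample-height
    corrections, grass-fuel quantile regression, and a Markov grove
    patch-dynamics simulator). Includes seeded synthetic-data generators that
    emulate every input with known ground truth, so the whole pipeline is
    testable without field or satellite data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
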