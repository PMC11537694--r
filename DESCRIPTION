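Package: priormap
Title: Conservation Prioritization from Species Distribution and Habitat Quality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for spatial conservation prioritization that
    combines a from-scratch regularized maximum-entropy species distribution
    model with a habitat-quality degradation model driven by distance-decay
    threat kernels. From species occurrence points and environmental rasters
    it produces habitat-suitability maps, habitat-quality maps, biodiversity
    hotspot classifications, and a protected-area gap analysis with tiered
    conservation priorities. Ships a synthetic-landscape generator so every
    stage is testable without external data, plus plain-text raster (ESRI
    ASCII grid) and GeoJSON polygon input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
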