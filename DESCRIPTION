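Package: agrosuit
Title: Agroforestry Land Suitability and Land-Use Change Analysis on Raster Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for FAO-style agroforestry land-suitability
    mapping and land-use/land-cover (LULC) change analysis on co-registered
    planar raster grids. Derives criterion layers (NDVI, tasseled-cap
    wetness, Horn slope, inverse-distance-weighted soil and precipitation
    surfaces), ranks them against configurable breakpoint tables, combines
    them by weighted overlay into S1/S2/S3 suitability classes restricted
    to agricultural land, accounts for class transitions between map dates
    along a rural-urban road gradient, and assesses accuracy with confusion
    matrices, Cohen's kappa, Landis-Koch agreement labels and tie-corrected
    Kendall rank correlation. A seeded synthetic scene generator provides
    complete miniature study areas so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
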