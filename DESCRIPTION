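Package: ehfsiter
Title: Two-Stage Spatial Siting of Elderly Healthcare Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans community elderly healthcare facilities (healthcare
    centers and clinics) inside large residential communities. Stage one
    screens a planar raster for candidate sites by overlaying land-use,
    existing-facility catchment and weighted kernel-density layers of the
    elderly population; stage two greedily selects sites under a maximal
    coverage objective with a demand-weighted distance (p-median)
    tie-break, and sizes each facility from the population it covers.
    Includes a seeded synthetic-community generator, survey
    summarisation, walk-time to service-radius conversion, and a
    reproducible end-to-end pipeline with GeoJSON and ASCII-grid raster
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
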