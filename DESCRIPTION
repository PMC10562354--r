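Package: priorigrid
Title: Multi-Resolution Spatial Conservation Prioritization on Raster Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates object-level boreal forest landscapes (clustered and
    sporadic tree species, downed deadwood, site-fertility classes),
    rasterizes them into stratified biodiversity feature stacks at a 16 m
    baseline, aggregates the stacks to coarser grids, ranks grid cells with
    a Zonation-style greedy additive benefit function (power-law benefit,
    z = 0.25), and quantifies the spatial and conservation error that raster
    coarsening introduces into reserve selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
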