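Package: walkaccess
Title: Walking-Based Geographic Accessibility to Primary Health Care
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models geographic accessibility to primary health care in rural
    districts where essentially all travel is on foot. Generates seeded
    synthetic districts (terrain, land cover, footpath network, buildings,
    facilities, GPS walking tracks), routes every household to its nearest
    primary health care centre and community health site over the footpath
    network with Dijkstra's algorithm, splits routes into 100 m segments,
    models walking speed with a mixed additive model (track-level random
    intercepts, non-linear slope smooth, rainfall, fatigue and land-cover
    effects), predicts door-to-facility travel time under dry and
    maximum-rainfall scenarios, and benchmarks against Euclidean-distance and
    friction-surface (least-cost raster) methods. Produces population-level
    accessibility tables and dual-vulnerability maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    splines,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
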