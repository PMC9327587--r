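Package: canopyflux
Title: Shortwave Radiant Flux Simulation for Forest Plots from Per-Tree Crown Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the clear-sky shortwave radiation regime of forest plots
    described by per-tree crown attributes (such as those segmented from airborne
    LiDAR). Computes solar geometry and clear-sky direct/diffuse irradiance with an
    Iqbal-type parameterization, models conifer crowns as cones and broadleaf crowns
    as semiellipsoids, triangulates crown surfaces by projected planar Delaunay
    triangulation, and traces a dense grid of parallel solar beams through the
    canopy with first-hit occlusion, single-bounce specular reflection and Snell
    refraction to obtain incident, reflected and transmitted radiant fluxes per
    facet and per plot over dates and hours. Includes a synthetic plot generator,
    hemispherical-photo and pyranometer cross-validation arithmetic, and OBJ/PLY
    mesh export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    optparse
Config/testthat/edition: 3
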