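Package: phylogrid
Title: Spatial Phylogenetics of Gridded Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for spatial phylogenetics on gridded
    presence-absence data: community matrix assembly from polygons or point
    occurrences; taxonomic and phylogenetic diversity and endemism metrics
    (species richness, weighted endemism, Faith's PD, Rosauer's PE, relative
    PD/PE, time-integrated lineage diversity, NODF nestedness); fixed-fixed
    and fixed-equiprobable community randomizations (swap, curveball, r0)
    with convergence diagnostics; CANAPE classification of neo-, paleo-,
    mixed and super endemism; phylogenetic beta diversity with
    turnover/nestedness decomposition and K-means regionalization;
    gradient-based climate-change velocity; and spatial regression
    (Moran's I correlograms, distance-band weights, simultaneous
    autoregressive error and lag models with AIC ranking). Includes a
    synthetic-data module generating pure-birth phylogenies, contiguous
    species ranges with controllable endemism hotspots, climate series and
    spatially autocorrelated responses with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    picante,
    phangorn,
    jsonlite,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
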