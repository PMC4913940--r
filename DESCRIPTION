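Package: econetclim
Title: Nestedness and Modularity of Ecological Networks Along Climate and
    Human-Impact Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the architecture of binary ecological
    networks (food webs, pollination and seed-dispersal webs) in relation to
    climate, climate-change velocity and human impact.  Computes NODF
    nestedness and bipartite/directed modularity (maximised by simulated
    annealing), standardises both metrics as Z-scores against
    degree-preserving null ensembles, derives climate-change velocities from
    paired current/palaeoclimate rasters, and fits ordinary least-squares and
    Moran-eigenvector spatially filtered regressions with AICc all-subsets
    selection, Akaike-weight variable importance and confidence-set model
    averaging.  Includes generators for synthetic networks, site tables and
    rasters with known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
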