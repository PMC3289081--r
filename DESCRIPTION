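Package: sprot
Title: Sphere-Based Protein Structure Similarity and Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Protein structure similarity built from spherical amino-acid
    neighbourhoods (aa-spheres). Each residue is represented by the residues
    whose heavy atoms fall within a fixed-radius ball around its alpha-carbon;
    local sphere similarities are calibrated against empirical score
    distributions and combined by global dynamic programming into a structure
    alignment scored with the TM-score heuristic. Includes an approximate
    k-nearest-neighbour access method for structure databases based on pivot
    tables with asymmetric lower bounds and similarity-preserving distance
    modifiers, retrieval-effectiveness metrics, and a deterministic synthetic
    structure generator for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
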