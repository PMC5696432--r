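Package: phylofloristics
Title: Phylogenetic Diversity, Endemism and Floristic District Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting floristic districts from tree-plot networks
    using taxonomic and phylogenetic diversity. Computes Fisher's alpha, Faith's
    phylogenetic diversity, standardized mean pairwise distance under an
    independent-swap null model, Sorenson and PhyloSorenson dissimilarity
    matrices with null expectations, weighted phylogenetic endemism,
    abundance-weighted evolutionary distinctiveness and clade-level abundance
    imbalance, non-metric multidimensional scaling, MRPP and Mantel permutation
    tests, and loess interpolation of per-plot metrics over a regular
    geographic grid. Includes a synthetic-landscape generator for power and
    calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    Matrix,
    cluster,
    mgcv,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
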