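Package: metaSNF
Title: Multi-Omics Subtyping via Metagene Similarity Network Fusion
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies molecular subtypes from multiple omics layers by
    first compressing each layer into a small set of metagenes with
    Kullback-Leibler non-negative matrix factorization (rank chosen by
    consensus-matrix cophenetic stability), then fusing per-layer sample
    similarity networks through iterative message passing, and finally
    partitioning samples by spectral clustering with eigengap model
    selection. Includes a synthetic multi-omics generator with planted
    subtype structure, a plain similarity-network-fusion baseline,
    clustering quality metrics (normalized mutual information,
    Davies-Bouldin, Calinski-Harabasz and Dunn indices), and the
    preprocessing filters commonly applied to tumor expression and
    methylation matrices (missing-rate filtering, k-nearest-neighbor
    imputation, log2(x+1) transform, low-variation filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
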