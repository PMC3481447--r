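Package: stmarker
Title: Steiner Tree-Based Marker Discovery in Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-based biomarker discovery by randomized Steiner trees.
    Given a protein-protein interaction network and a set of differentially
    expressed seed genes, repeatedly connects the seeds into a single tree
    under randomly perturbed edge weights and takes the union of internal
    tree vertices as Steiner-tree-based markers (STMs). Includes the
    shortest-path 2-approximation Steiner heuristic with an exact
    brute-force solver for small instances, hypergeometric (Fisher's exact)
    overlap statistics computed in log space, repeated stratified
    cross-validation evaluation of marker sets with logistic regression or
    linear support vector machines, and generators for synthetic scale-free
    networks, planted connector genes and two-class expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    e1071,
    pROC,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
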