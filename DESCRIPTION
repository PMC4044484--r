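Package: bicledit
Title: Weighted Bi-Cluster Editing of Bipartite Similarity Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms a weighted bipartite similarity graph into a
    vertex-disjoint union of bi-cliques at minimum total edge-modification
    cost. Implements an exact fixed-parameter branching solver over induced
    four-vertex paths (P4s) with permanent/forbidden edge marking, a
    polynomial greedy edge-deletion heuristic driven by a transitivity
    deviation score, a planted-bicluster random graph generator with
    two-Gaussian edge weights, and an exhaustive set-partition oracle for
    verification on small instances. Includes readers and writers for
    weighted edge-list TSV files (including -log10 p-value association
    tables) and a command-line front end that dispatches solvers per
    connected component.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
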