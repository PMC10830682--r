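Package: rankedSPR
Title: Ranked Subtree Prune and Regraft Treespaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data structures and algorithms for the two treespaces of ranked
    phylogenetic trees induced by horizontal subtree prune and regraft (HSPR)
    moves, alone or together with rank moves (RSPR). Provides the cluster
    representation of ranked trees with validation, enumeration and uniform
    random generation, move validation and application in both the edge-set
    and the cluster form, exact distances by breadth-first search, a bottom-up
    path approximation with a 2(n-2) guarantee, a leaf-parent lower bound,
    shortest-path enumeration and normalisation (rank moves first, monotone
    move ranks), exhaustive small-n treespace graphs with orbit-reduced
    diameter computation, and machine-checkable audits of structural
    properties of these spaces (cluster property counterexamples, cherry
    preservation, distance invariance under cherry-leaf deletion, caterpillar
    metric equality, leaf-addition distance collapse). Includes parsers and
    writers for the cluster-list text format and ultrametric Newick, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
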