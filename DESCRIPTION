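Package: pkncompendium
Title: Assembly and Structural Analysis of Signalling Pathway Interaction
    Compendia
Version: 0.1.0
Authors@R:
    person("Jordan", "Kincaid", email = "jkincaid@example.org",
           role = c("aut", "cre"))
Description: Builds ensemble prior-knowledge networks for signal transduction
    from multiple pathway and interaction databases, and analyses their
    structure. Pathway gene sets and interaction edge lists (Cytoscape SIF or
    annotated tables) are merged into a single provenance-annotated
    compendium. Analyses include per-gene topology (degree, betweenness,
    pathway multiplicity) with hypergeometric enrichment landscapes, pairwise
    pathway similarity (Jaccard) with hierarchical ordering, cross-database
    edge-weight and edge-consistency summaries, pathway modularity against a
    membership-preserving randomization null with Mann-Whitney testing, and
    bounded simple-path enumeration between ligands and sentinel effectors
    with bypass-edge classification and linear-scaffold expansion. A
    synthetic-data generator with planted ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
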