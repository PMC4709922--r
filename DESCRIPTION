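Package: logicnet
Title: Gene Logic Network Inference from Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers "logic networks" of gene triplets from two-condition
    expression matrices. Expression vectors are discretized onto a
    multi-valued (2k-level) scale, every ordered gene triplet (A,B) -> C is
    scored with an entropy-based uncertainty coefficient against ten
    min/max/negation logic functions, and triplets that predict their
    target better than either source alone are kept as directed
    hyperedges. The package computes structural parameters generalized to
    these hypergraphs (fractional degrees, doublet clustering
    coefficients, AND/OR/XOR shortest-hyperpath distances, standard
    betweenness), detects communities by greedy modularity maximization,
    and compares two condition-specific networks to nominate structural
    key genes. A synthetic-data generator with planted differential genes
    and logic triplets makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
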