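Package: linkerity
Title: Linker Protein Detection in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies 'linker' proteins that bridge functional sub-networks of
    a protein-protein interaction network. Builds confidence-filtered interaction
    graphs from STRING- or BioGRID-style tab-separated snapshots, annotates nodes
    with functional categories, ranks nodes by betweenness centrality with
    average-tie ranking, and computes the linkerity score: the ratio of a
    protein's centrality rank inside its functional sub-network to its rank among
    sub-network members evaluated in the merged core network. Includes
    degree-preserving and fully random rewiring null models for functional
    modularity, edge-perturbation robustness protocols, k-clique percolation
    community composition, neighbour-annotation heterogeneity analysis, and a
    synthetic-network generator with planted modules and planted linkers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
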