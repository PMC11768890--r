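Package: phytointeract
Title: Multi-Omics Analysis of Compound Interactions in Botanical Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying additive, synergistic and
    antagonistic interactions between constituent compound groups of a
    botanical extract using bulk transcriptomics and targeted metabolomics.
    Implements count filtering, TMM normalization, log-CPM with precision
    weights, moderated per-gene linear models, a treatment-interaction
    contrast with a positive/negative/additive classification, weighted
    co-expression and co-abundance module detection (soft-threshold
    adjacency, topological overlap, eigenfeatures, module membership),
    hypergeometric over-representation analysis, knowledge-based
    integration of the two omics layers on a composite metabolite-protein
    network with random-walk community detection, and a network-proximity
    permutation test on protein-protein interaction graphs. Ships a
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    limma,
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
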