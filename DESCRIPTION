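Package: konet
Title: Community-Level Metabolic Networks from Metagenomic Functional Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs directed enzyme-level (KEGG Orthology) metabolic
    networks for microbial communities from metagenomic functional annotation
    profiles. Estimates enzymatic gene abundances by even-split counting over
    tied best hits and multi-KO reference sequences, serializes abundance
    tables as BIOM 1.0 JSON, induces state-specific subnetworks carrying
    abundances as node attributes, computes node topology (degree,
    betweenness, clustering coefficient, PageRank) together with its
    correlation with abundance, and scores per-enzyme differential abundance
    between two biological states by odds ratio, mean-rank difference, or
    Jensen-Shannon divergence, exporting enriched/depleted colored networks
    to GraphML and Cytoscape JSON. Includes a synthetic-data generator with
    known ground truth and a command-line interface over the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
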