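Package: ddslice
Title: Frequency Slicing and Discrete Derivatives for Literature
    Co-Occurrence Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines co-occurrence structure from biomedical literature
    corpora in which each citation carries a set of controlled descriptor
    terms (MeSH headings or database keywords).  Builds descriptor-pair
    frequency tables, slices them by frequency threshold, computes level
    distributions (the set of pairs at an exact frequency) and set-valued
    discrete derivatives of any order, and verifies executably that those
    derivatives are constant across orders.  Supports intersecting the
    pair tables of two disease corpora, filtering by a term lexicon (for
    example a table of Chinese herbs), ranking lexicon terms by record
    occurrence, and seed-term cross-queries.  Extracts wheel-shaped (star)
    motifs and hub-intersection subnetworks from the resulting undirected
    graphs and exports them in Cytoscape-ready SIF, GraphML, or edge-table
    formats.  A seeded synthetic-corpus generator with planted pairs and
    stars makes every operation testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    utils,
    stats,
    data.table,
    igraph,
    xml2,
    jsonlite,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Software, DataImport, Visualization
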