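Package: axonmod
Title: Network Medicine Toolkit for Disease Module Detection and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing disease genes on a protein-protein
    interaction network and comparing the resulting disease modules.
    Implements parsing and confidence filtering of scored interactome
    tables, largest-connected-component and shortest-distance localization
    statistics with randomization nulls, the network separation score
    s_AB between two gene sets with a degree-aware null model, seed-weighted
    DIAMOnD module expansion based on hypergeometric connectivity
    significance, Wang-method Gene Ontology semantic similarity with
    best-match-average combination, and hypergeometric over-representation
    analysis of pathway collections with Benjamini-Hochberg control and
    Jaccard-based pathway grouping. Includes synthetic generators for
    scale-free networks, planted modules with controllable cohesion and
    overlap, toy ontologies, annotation sets, and pathway collections, so
    the full pipeline can be exercised and calibrated without external
    downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
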