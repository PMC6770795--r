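Package: harmonet
Title: Cross-Species Network Analysis of Ultradian and Circadian Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying genes that oscillate with 8-h, 12-h and 24-h
    periods across species. Implements period-class labelling, resolution of
    one-to-many homolog candidates by a score priority cascade, chromosomal
    co-localization networks (same-chromosome cliques) with cross-species
    intersection and a conservation score, a randomized-set permutation test
    for the connectivity of a gene set to a protein-protein interaction
    subnetwork, and rank-based multi-group comparison of protein energy
    features (Kruskal-Wallis with an optional residue-number adjustment,
    Dunn's post hoc test with false-discovery-rate correction, Spearman
    correlation matrices). A seeded synthetic-data generator produces
    two-species chromosome assignments with tunable co-localization
    conservation, homolog candidate tables, interaction networks with
    planted enrichment, and per-protein energy tables, so the whole pipeline
    can be exercised and calibrated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
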