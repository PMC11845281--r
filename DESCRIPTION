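Package: koenrich
Title: Ortholog-Based KEGG Pathway Over-Representation Analysis for
    Non-Model Organisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline gene-set over-representation analysis for organisms
    that lack curated annotation databases. Genes are linked to KEGG
    pathways through KEGG Orthology (KO) identifiers obtained from
    ortholog annotators (eggNOG-mapper, BlastKOALA, KAAS); up to three
    annotation sources can be merged by union or intersection. Foreground
    gene sets are tested against a background universe with the
    hypergeometric upper tail (equivalently a one-sided Fisher exact
    test), adjusted with the Benjamini-Hochberg procedure, and reported
    as a ranked table together with barplot, lollipop, heatmap, treeplot,
    gene-pathway network, UpSet and literature-trend visualizations, plus
    red-highlighted KGML pathway diagrams. A seeded synthetic-data module
    generates catalogs, annotations and spiked gene lists so the whole
    pipeline is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
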