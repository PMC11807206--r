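Package: poolscreen
Title: Simulation and Analysis of Pooled shRNA Survival Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled lentiviral shRNA enrichment screens
    read out by deep sequencing of hairpin barcodes. Provides a library
    designer and screen-design budget calculator (coverage, MOI, gDNA mass), a
    negative-binomial count simulator with FASTQ emission, mismatch-tolerant
    barcode quantification, CPM normalization, an exact conditional
    negative-binomial test for differential shRNA representation with
    moderated dispersion and per-pool Benjamini-Hochberg control, a multi-pool
    gene-level hit-calling rule, counter-screen subtraction, and
    hypergeometric over-representation analysis against GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
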