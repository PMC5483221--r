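Package: crefam
Title: Comparative Gene-Family Expression and Cis-Regulatory Element Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative regulatory analysis of plant gene families:
    meta-expression profiling across tissue compendia with expression-pattern
    classification, Pearson co-expression grouping, degenerate (IUPAC) consensus
    scanning of promoter sets, group-common and group-unique cis-regulatory
    element calling, neighbor-joining phylogenies with bootstrap supports and
    subgroup assignment, and protein-interaction networks overlaid with
    co-expression. Includes a synthetic-data generator that emulates a tissue
    expression compendium, promoter sets with planted motifs, protein families
    evolved on a known tree, and hub-structured interaction tables, so every
    analysis can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
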