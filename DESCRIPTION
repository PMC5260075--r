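Package: bartrie
Title: Trie-Based Barcode-Seq Mapping and Pooled Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mapping and analysis of multiplexed barcode sequencing data from
    pooled library screens (shRNA, sgRNA, barcoded yeast deletion strains).
    Reads are collapsed to unique sequences and mapped to a barcode library
    with a trie-based imperfect matching engine that allows mismatches,
    insertions and deletions, uses primer alignment to correct barcode
    position shifts, and demultiplexes variable-length 5' indices. Library
    quality control detects erroneous barcodes (pool sequences that differ
    from their design) and reports all pairwise barcode similarities under
    static and dynamic sequence-length comparison. Case versus control
    statistics provide pseudocounted ratio normalization, low-count
    filtering, per-barcode fold-change and z-scores, per-gene clustering
    with quarter-rule off-target removal, ranking and time-series
    fold-changes. A seeded synthetic-data generator produces libraries,
    error-bearing reads and screens with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
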