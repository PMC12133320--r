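Package: mpraqc
Title: Quality Control and Activity Quantification for Massively
    Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stepwise pipeline for processing massively parallel
    reporter assay (MPRA) sequencing data: paired-end read merging,
    barcode-to-oligo association mapping with purity-based conflict
    resolution, DNA and RNA barcode counting with coverage and
    downsampling-saturation diagnostics, per-oligo regulatory activity as
    the ratio of summed normalized RNA to plasmid counts, replicate
    concordance, risk-flagged quality-control reports against editable
    reference ranges, and export of count matrices for downstream
    statistical tools. Includes a ground-truthed synthetic read generator
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    stringi,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
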