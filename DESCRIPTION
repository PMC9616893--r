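Package: bfcompose
Title: Composed Boolean Functions in Bipartite Models of Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the logic rules available to genes in bipartite
    Boolean models of transcriptional regulation, where genes act through
    intermediate transcriptional regulators (single transcription factors,
    heteromeric complexes, or cis-regulatory elements). Provides exhaustive
    enumeration of the composed Boolean functions compatible with a
    composition structure (with or without closure under input permutation),
    enumeration and membership tests for biologically meaningful function
    classes (unate, canalyzing, nested canalyzing, read-once), set-overlap
    analytics across composition structures, enrichment statistics for
    catalogs of empirically observed update rules with exact binomial tail
    p-values, and an enhancer-transcription-factor co-binding analysis based
    on the midpoint-plus-summit containment rule for ChIP-seq peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
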