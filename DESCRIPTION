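Package: sigdomnet
Title: Signaling-Domain Network Analysis of Epigenetic and Genetic
    Alterations in Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls candidate functional driver genes from matched tumor/normal
    DNA methylation, expression, copy-number and mutation data, maps them onto
    a signaling-domain-annotated protein interaction network, and tests for
    differential network topology and signaling-domain enrichment, including
    pathway-level Fisher's-combined meta-analysis across cancer types and
    co-expression consistency analysis with epigenetic enzymes. Includes a
    synthetic multi-omic cohort and interactome generator with planted,
    domain-biased alteration classes for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
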