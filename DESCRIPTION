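Package: tirscape
Title: Comparative Analysis of Plant TIR-Domain Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative genomics of plant
    Toll/Interleukin-1 receptor (TIR) domain proteins. Assembles domain
    architectures (TNP, TNL, TN, TIR-only) from HMM domain-search hit
    tables with overlap deduplication and per-class length minima;
    filters multiple-sequence-alignment columns by gap fraction and
    summarises per-column residue frequencies against an ungapped
    reference; detects taxonomically shared, well-supported clades on
    phylogenies annotated with ultrafast bootstrap and SH-aLRT support;
    builds orthogroup presence-absence matrices and extracts rows
    matching strict co-occurrence patterns; and tests the association
    between gene expression and immune-trigger status of RNA-seq samples
    with one-sided Fisher exact tests and Bonferroni correction. Seeded
    synthetic-data generators with planted ground truth allow every
    pipeline stage to be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
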