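Package: ocgiturnover
Title: Comparative Turnover Analysis of Orphan CpG Islands and Enhancer Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of orphan CpG island (oCGI)
    turnover across species and its association with enhancer-associated
    histone modification peak turnover and gene expression change. Implements
    a windowing CpG island caller over repeat-masked genome sequence, orphan
    filtering against gene-associated annotation (including a human-intermediate
    cross-species filter), a liftOver-style block coordinate map with
    orthologous-site construction and gain/loss polarization, genomic shuffle
    and label-permutation null models for interval overlap enrichment,
    signal-matched and expression-matched resampling tests, GREAT-rule
    regulatory-domain gene assignment, and seeded synthetic multi-species data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
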