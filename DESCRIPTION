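Package: concordkit
Title: Multi-Platform Variant-Call Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing single-nucleotide variant callsets obtained
    from multiple sequencing platforms on the same sample: Venn partitioning
    of per-platform calls, nine-category classification of why a platform
    missed a site, false-positive estimation from singleton calls,
    Poisson depth-of-coverage modelling and filtering, GC-bias window
    profiling, uniquely-mappable-region ("uniqueome") computation by
    self-masking fragment tiling, duplicate-read marking, and slop-tolerant
    indel interval matching. Includes a synthetic multi-platform data
    generator with planted miss-causes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
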