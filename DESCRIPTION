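Package: isomirseq
Title: IsomiR Profiling and Senescence-Trend Analysis from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for microRNA isoform (isomiR) analysis
    from small RNA sequencing reads: native 3' adapter trimming, ungapped
    unambiguous alignment to hairpin precursors, signed-offset isomiR
    nomenclature ("+1|-2"), six-way isomiR classification with detection of
    non-templated 3' additions and uridylation, reads-per-million
    quantification with an arm-aligned denominator, category proportion
    tables with two-proportion z-tests, negative-binomial Wald and
    likelihood-ratio differential-expression testing across an ordered
    three-condition design with trend-shape classification (linear versus
    U-shaped), 5' seed-shift target prediction on 3'UTRs and Fisher
    gene-set enrichment. A synthetic-data module generates reads, count
    matrices, UTRs and gene sets with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
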