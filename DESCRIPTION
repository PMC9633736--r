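Package: msrtools
Title: Mapping-Friendly Sequence Reductions for Long-Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for streaming sequence reductions (SSRs), a generalization
    of homopolymer compression in which an order-l window function rewrites
    DNA sequences before read mapping. Provides the transformation engine
    with coordinate lift-over between original and reduced sequence spaces,
    construction, equivalence testing, exact counting and exhaustive
    enumeration of the restricted (reverse-complement-core-insensitive)
    order-2 reductions, mapq-threshold evaluation curves with a
    mapeval-style placement-correctness criterion, the selection procedure
    for mapping-friendly sequence reductions (MSRs), and a seeded synthetic
    data generator (genome, nanopore-like reads with encoded truth, and PAF
    mappings) so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    rlang,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
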