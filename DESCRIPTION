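Package: antisenseq
Title: Strand-Specific Antisense Transcription Analysis with Spike-In
    Normalized ChIP Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies stranded RNA-seq reads against a gene annotation
    into sense, antisense and intergenic categories, computes
    replicate-averaged RPKM expression tables, and calls differential
    antisense transcription with a fold-change plus noise-floor rule
    across a multi-strain, multi-treatment design. Provides
    hypergeometric gene-set overlap, Mann-Whitney synergy and Fisher
    term-enrichment statistics, spike-in normalized ChIP signal and
    ratio tracks, anchored and gene-scaled metagene matrices,
    occupancy-based gene clustering, and a deterministic synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
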