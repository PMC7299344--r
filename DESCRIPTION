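Package: drmscan
Title: Discovery of Damage-Responsive, Maturity-Silenced Enhancers from
    Chromatin Accessibility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify candidate damage-responsive, maturity-silenced
    (DRMS) enhancers from ATAC-seq style chromatin accessibility data.
    Builds a union peak atlas from ranked per-condition peak calls, counts
    fragments over atlas peaks, tests peaks for differential accessibility
    between conditions with a negative-binomial Wald test and
    Benjamini-Hochberg correction, classifies peaks into damage-responsive,
    maturity-silenced and DRMS sets, annotates peaks with nearby genes and
    genomic feature categories, and screens enhancer sequences for conserved
    blocks and transcription-factor binding motifs. A synthetic-data module
    simulates a staged damaged/undamaged replicate design with
    negative-binomial counts, responder dilution and planted ground truth,
    so every stage of the pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
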