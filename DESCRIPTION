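Package: pcgstates
Title: Chromatin States of Polycomb Target Genes from Tiling-Array ChIP Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for probe-level ChIP/Input tiling-array signal
    at Polycomb/Trithorax target genes: replicate averaging and smoothing of
    fold-ratio tracks, max-gap/min-run segmentation into bound regions,
    definition of Polycomb target domains (Class I/II) and computational
    Polycomb Response Elements, gene-activity calls from RNA Pol II and
    H3K4me3 promoter signal, a rule-based four-way chromatin-state
    classification (repressed, active, balanced, void), cross-condition
    comparison (region matching, state-change detection, saturation and
    overlap statistics, knockdown quantification, anchor-centered profiles),
    qRT-PCR-style relative expression with an exact rank-sum test, and a
    synthetic-data generator that plants ground-truth states so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
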