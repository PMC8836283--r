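Package: promtss
Title: Transcription Start Site Selection and Promoter Characterization
    for Draft Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects one best-supported transcription start site (TSS) per
    gene model from candidate predictions using a gamma prior on 5'UTR
    length fitted by the method of moments, and characterizes the resulting
    promoters: core-motif (TATA-box, initiator CA) sliding-window frequency
    profiles, CG-skew, nearest-neighbor DNA duplex free-energy profiles,
    MATCH-style position weight matrix scanning, and coding-sequence GC3
    analytics (positional gradient and slope, quantile classes, class
    comparisons).  A synthetic genome/annotation generator with planted
    ground truth allows every stage to be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
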