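Package: folliclemap
Title: Cross-Species Comparative Analysis of Follicle Development
    Transcriptomes and Regulatory Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing ovarian follicle development across
    species from bulk granulosa- and theca-cell transcriptomes and
    H3K27ac regulatory data. Integrates per-species FPKM matrices over
    one-to-one orthologs with location-scale batch correction, matches
    developmental stages across species by dynamic time warping over
    Spearman-correlation cost matrices, discovers stage- and
    species-specific follicle-development genes and biological
    processes with negative-binomial Wald tests and hypergeometric
    enrichment, calls super-enhancers from peak and signal tracks with
    a rank-signal hockey-stick cutoff, infers the super-enhancer-based
    core transcription-factor regulatory network with harmonic
    closeness centrality and regulatory circuits, and scores clade
    specificity of enhancer regions from multiple-alignment gap
    patterns. Ships seeded synthetic-data generators with planted
    ground truth so the whole pipeline is testable end to end without
    external downloads.
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
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
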