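Package: h2bdyn
Title: H2B Monoubiquitination Domain Dynamics from Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of monoubiquitinated H2B (H2Bub) dynamics
    during Arabidopsis de-etiolation. Calls H2Bub-enriched domains from
    tiling-array log-ratio signal with a two-state Gaussian hidden Markov
    model, calls differentially enriched domains between time points with a
    moderated TileMap-style statistic, decides per-gene marking status by the
    central-40%-of-transcribed-region rule, analyses differential expression
    in wild type and the hub1-3 mutant, classifies light-response kinetics,
    partitions expression patterns with a self-organizing map, and integrates
    chromatin and expression (metagene profiles, cross-tabulations, quadrant
    correlations, set over-representation, candidate-gene selection). A
    synthetic-data generator with planted domains and expression effects
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    limma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    readr
Config/testthat/edition: 3
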