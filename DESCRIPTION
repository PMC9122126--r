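Package: hotspotr
Title: Mining Diversity Hotspots of Anti-Phage Systems in Prophages and
    Phage Satellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers diversity hotspots of anti-phage defense systems
    located between conserved anchor genes of prophages and phage
    satellites (such as the psu-int locus of P4-like elements and the
    gpQ-gpA locus of P2-like phages). Provides exact affine-gap
    Smith-Waterman protein search with Karlin-Altschul E-values,
    strand-aware downstream-window extraction of anchor-to-closer loci,
    greedy bidirectional-coverage protein clustering, gene-arrangement
    frequency and curation statistics, grouping of arrangements into
    genetic systems, and a quorum/loner co-localization detector for
    multi-gene defense systems scored against domain profiles. A
    synthetic-corpus generator with a planted-truth ledger supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    tibble,
    tidyr,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
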