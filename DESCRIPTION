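Package: markermine
Title: Marker-Gene Mining of Metagenomes with BLAST-Score-Ratio Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A read-based pipeline for profiling nitrogen- and methane-cycle
    marker genes in metagenomes. Reads are quality-trimmed, screened against
    curated amino-acid reference sets by six-frame translated local alignment,
    and filtered with a two-database BLAST-score-ratio (BSR) statistic with
    per-family cutoffs. Homologous gene pairs (hao/hdh, narG/nxrA) are
    resolved by read mapping and a second BSR round, reads are classified by
    a lowest-common-ancestor rule, counts are normalized to the single-copy
    rpoB gene, and near full-length genes are reconstructed by iterative
    mapping. A synthetic-community simulator with per-read ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
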