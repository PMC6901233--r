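Package: pbsnj
Title: Multi-Population Branch Statistics and Genic Enrichment Scans for
    Local Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selection scans based on between-population allele frequency
    differentiation. Computes the signed difference in derived allele
    frequency (delta) between population pairs and its genic enrichment
    spectrum, the multi-population branch statistic PBSnj (per-SNP
    neighbor-joining on pairwise Hudson Fst distances transformed to drift
    time), weighted block-jackknife confidence intervals (Busing delete-m_j),
    a structured-coalescent simulator with per-population background-selection
    (B value) scaling and sum-of-squared-differences fitting of the best B,
    ranked-block sweep counting, and resampling-based gene-set enrichment
    with gene-length bias correction. Includes a synthetic data generator
    emulating multi-population drift with block structure and planted sweeps
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
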