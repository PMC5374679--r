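Package: poolcline
Title: Pool-Seq Population Genomics Along Environmental Clines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled resequencing (Pool-seq) data sampled along an
    environmental gradient: parsing of PoPoolation2-style sync allele-count
    tables, window-based estimation of nucleotide diversity, Watterson's theta
    and Tajima's D with min-count and coverage-truncation corrections, per-SNP
    and per-gene F_ST outlier scans with Fisher exact tests and functional
    classification of SNPs, DISTATIS ordination of quantile distance matrices,
    neighbor-joining trees, Mantel tests, f3/f4 admixture statistics with block
    jackknife standard errors, covariance-controlled gene-environment
    association scoring, GO-term enrichment with the elim algorithm, and
    small-sample ecophysiological trait statistics. A seeded synthetic-data
    generator emulating a clinal Pool-seq study design makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
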