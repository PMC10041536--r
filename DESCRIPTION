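Package: tempsel
Title: Generation-Resolved Selection-Signature Analysis for Closed Breeding
    Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a closed breeding line
    under sex-specific truncation selection on an additive polygenic trait,
    and a generation-resolved pipeline for dissecting the selection response:
    temporal allele-frequency-difference (dAF) binning with annotation-category
    enrichment, Weir-Cockerham Fst and cross-population extended haplotype
    homozygosity (XP-EHH) scans in sliding windows with empirical-quantile
    thresholds, EMMAX-style mixed-linear-model association with spectral REML,
    linkage-disequilibrium refinement of candidate regions, nucleotide
    diversity and allele-frequency trajectories, and a copy-number-variant
    relative-frequency-difference screen.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    vcfR,
    IRanges,
    S4Vectors,
    rtracklayer,
    cluster,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
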