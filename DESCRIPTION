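Package: tepop
Title: Population Genetics of Transposable Element Insertion Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curation and population-genetic analysis of transposable element
    (TE) presence/absence polymorphisms detected from short-read data in
    population samples, such as resequencing panels of Aedes aegypti. Merges
    raw per-sample reference-TE absence calls and non-reference insertion
    calls into polymorphic loci (same family, within 1 kb), resolves
    hybrid-family calls by read support, applies activity/frequency/length
    filters with full bookkeeping, builds binary presence/absence genotype
    matrices, and computes site frequency spectra, joint SFS, pairwise FST on
    carrier proportions, PCA, cross-population differentiation scans,
    gene/exon annotation overlays, and dual-encoding linkage disequilibrium
    between TE insertions and candidate insecticide-resistance SNPs. Includes
    a Balding-Nichols synthetic-data generator with ground-truth sidecars so
    the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
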