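Package: sweepscan
Title: Two-Population Selective Sweep Scans from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps between two groups of diploid samples
    from multi-sample VCF genotypes and phased haplotypes. Implements per-SNP
    Weir-Cockerham FST with 50 kb windowed averaging and Z-transformation,
    cross-population extended haplotype homozygosity (XP-EHH) from EHH/iHH
    kernels, pooled heterozygosity (Hp) in 10 kb windows, Tajima's D, linkage
    disequilibrium r2 decay, threshold-based sweep-region calling with gene
    intersection and hypergeometric enrichment, allele-sharing distances with
    neighbor-joining trees, and a two-population hard-sweep simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
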