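# Programmatic fixtures: small genotype/haplotype objects and VCF text.

# gm with explicit dosage rows (samples x sites); default 5v5 design.
toy_gm <- function(dosages, positions = NULL, chrom = "chr1",
                   ref = NULL, alt = NULL, effect = NULL,
                   n_a = ceiling(nrow(dosages) / 2)) {
  n <- nrow(dosages)
  S <- ncol(dosages)
  samples <- sprintf("s%02d", seq_len(n))
  groups <- stats::setNames(rep(c("A", "B"), c(n_a, n - n_a)), samples)
  if (is.null(positions)) positions <- seq_len(S) * 100
  sites <- tibble::tibble(
    chrom = chrom, pos = positions,
    ref = ref %||% rep("A", S), alt = alt %||% rep("G", S),
    effect_class = effect %||% rep(NA_character_, S)
  )
  geno_matrix(dosages, sites, samples, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random two-group genotype matrix (no missing unless miss > 0)
random_gm <- function(n_per_group = 5, S = 20, miss = 0) {
  n <- 2 * n_per_group
  p <- stats::runif(S, 0.05, 0.95)
  d <- matrix(stats::rbinom(n * S, 2, rep(p, each = n)), nrow = n)
  if (miss > 0) d[stats::runif(length(d)) < miss] <- NA
  # ensure at least one called genotype pattern per group stays valid
  toy_gm(d, n_a = n_per_group)
}

random_hap <- function(n_hap = 10, S = 12, spacing = 500) {
  hap <- matrix(stats::rbinom(n_hap * S, 1, 0.5), nrow = n_hap)
  samples <- rep(sprintf("s%02d", seq_len(n_hap / 2)), each = 2)
  hap_matrix(hap, cumsum(rep(spacing, S)), "chr1", samples)
}

# VCF text fixture: 3 samples, 5 biallelic SNPs, 1 indel, 1 triallelic.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    paste0("##INFO=<ID=ANN_CLASS,Number=1,Type=String,",
           "Description=\"effect\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "T", ".", "PASS",
            "ANN_CLASS=nonsynonymous", "GT", "0|1", "./.", "1/1"),
          collapse = "\t"),
    paste(c("chr1", "300", ".", "G", "GA", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0/0"), collapse = "\t"),
    paste(c("chr1", "400", ".", "T", "A,C", ".", "PASS", ".", "GT",
            "0/1", "0/2", "1/1"), collapse = "\t"),
    paste(c("chr1", "500", ".", "T", "C", ".", "PASS", ".", "GT",
            "./1", "0/0", "1/1"), collapse = "\t"),
    paste(c("chr1", "600", ".", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "0/0", "0/1"), collapse = "\t"),
    paste(c("chr1", "700", ".", "G", "C", ".", "PASS", ".", "GT",
            "1/1", "0/1", "0/0"), collapse = "\t")
  ), path)
  path
}

# phased two-chromosome fixture: 2 samples, 3 + 2 sites, all "0|1"
write_phased_vcf <- function(path, break_record = FALSE) {
  rec <- function(chrom, pos, gt1, gt2) {
    paste(c(chrom, pos, ".", "A", "G", ".", "PASS", ".", "GT", gt1, gt2),
          collapse = "\t")
  }
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##contig=<ID=chr2,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
    rec("chr1", 100, "0|1", "0|1"),
    rec("chr1", 200, if (break_record) "0/1" else "0|1", "0|1"),
    rec("chr1", 300, "0|1", "0|1"),
    rec("chr2", 150, "0|1", "0|1"),
    rec("chr2", 250, "0|1", "0|1")
  ), path)
  path
}

fixture_groups3 <- c(S1 = "A", S2 = "A", S3 = "B")
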