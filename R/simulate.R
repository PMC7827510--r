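#' Configuration for the two-population sweep simulator
#'
#' Defaults mirror the study design the package targets: two groups of five
#' diploid samples, a neutral SFS-distributed background shared between
#' groups, and one planted hard sweep in group B (the high-fecundity
#' analog) on a 2 Mb chromosome.
#'
#' @param n_per_group diploid samples per group (default 5).
#' @param chrom_specs tibble with `name` and `length` (bp).
#' @param snp_spacing mean bp between SNPs (Poisson-process spacing,
#'   default 200).
#' @param sfs_shape exponent `alpha` of the background site frequency
#'   spectrum: derived-allele count k (out of the 4*n_per_group
#'   chromosomes) is drawn with probability proportional to `1/k^alpha`;
#'   `alpha = 1` is the neutral expectation.
#' @param sweeps tibble of planted sweeps: `chrom`, `center`, `half_width`
#'   (bp), `selected_group` ("A"/"B"), `carrier_freq_selected`,
#'   `carrier_freq_other`, `core_mutation_rate`. `NULL` for a neutral
#'   genome.
#' @param missing_rate per-call probability of masking a genotype (default
#'   0; haplotypes are always complete).
#' @param coding_fraction fraction of sites given a coding effect class
#'   (for exercising variant ranking; default 0.02).
#' @param seed mandatory RNG seed.
#' @return A `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(n_per_group = 5,
                             chrom_specs = tibble::tibble(
                               name = c("chr1", "chr2"),
                               length = c(2e6, 2e6)),
                             snp_spacing = 200,
                             sfs_shape = 1,
                             sweeps = default_sweeps(),
                             missing_rate = 0,
                             coding_fraction = 0.02,
                             seed = 1) {
  stopifnot(n_per_group >= 2, all(chrom_specs$length >= 10 * snp_spacing),
            !is.null(seed))
  if (!is.null(sweeps) && nrow(sweeps) > 0) {
    for (chr in unique(sweeps$chrom)) {
      s <- sweeps[sweeps$chrom == chr, ]
      s <- s[order(s$center), ]
      if (nrow(s) > 1) {
        starts <- s$center - s$half_width
        ends <- s$center + s$half_width
        if (any(starts[-1] < ends[-nrow(s)])) {
          stop("overlapping sweep intervals on ", chr, call. = FALSE)
        }
      }
    }
    stopifnot(all(sweeps$carrier_freq_selected > sweeps$carrier_freq_other),
              all(sweeps$carrier_freq_selected <= 1),
              all(sweeps$carrier_freq_other >= 0))
  }
  structure(list(n_per_group = n_per_group, chrom_specs = chrom_specs,
                 snp_spacing = snp_spacing, sfs_shape = sfs_shape,
                 sweeps = sweeps, missing_rate = missing_rate,
                 coding_fraction = coding_fraction, seed = seed),
            class = "sweep_sim_config")
}

#' Default planted sweep: 50 kb in group B at 1 Mb on chr1
#'
#' Carrier frequencies 0.9 (selected group) versus 0.1 reproduce a
#' near-fixed hard sweep still polymorphic in the population as a whole.
#'
#' @return One-row sweep tibble.
#' @export
default_sweeps <- function() {
  tibble::tibble(chrom = "chr1", center = 1e6, half_width = 25000,
                 selected_group = "B", carrier_freq_selected = 0.9,
                 carrier_freq_other = 0.1, core_mutation_rate = 0.01)
}

#' Simulate a two-group genotype and haplotype dataset with planted sweeps
#'
#' Background sites are unlinked: positions follow a Poisson process with
#' the configured mean spacing, the derived-allele frequency of each site
#' is drawn from the configured SFS and shared between the groups (so
#' neutral FST is ~0 in expectation), and each haplotype draws its
#' background alleles independently. Inside each sweep interval a fixed
#' core haplotype is planted: each haplotype copies it with the
#' group-specific carrier probability (copied alleles flipped at
#' `core_mutation_rate`), producing elevated FST, depressed heterozygosity
#' and extended haplotype homozygosity in the selected group. Genotypes
#' are the sums of the two haplotypes per sample. Fully reproducible from
#' the seed.
#'
#' @param config a [sweep_sim_config()].
#' @return List with `gm` (a [geno_matrix()]), `haps` (named list of
#'   [hap_matrix()] per chromosome), `truth` (tibble of planted intervals,
#'   0-based half-open) and the `config`.
#' @export
simulate_sweep_data <- function(config) {
  stopifnot(inherits(config, "sweep_sim_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  samples <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  groups <- stats::setNames(rep(c("A", "B"), each = n), samples)
  n_hap <- 4 * n
  hap_group <- rep(rep(c("A", "B"), each = 2 * n))
  K <- n_hap  # frequency grid: allele count out of all simulated copies
  k_prob <- (1 / seq_len(K - 1)^config$sfs_shape)
  k_prob <- k_prob / sum(k_prob)

  haps <- list()
  sites_all <- list()
  geno_cols <- list()
  for (ci in seq_len(nrow(config$chrom_specs))) {
    chr <- config$chrom_specs$name[ci]
    len <- config$chrom_specs$length[ci]
    gaps <- stats::rexp(ceiling(2 * len / config$snp_spacing),
                        rate = 1 / config$snp_spacing)
    pos <- unique(round(cumsum(gaps)))
    pos <- pos[pos >= 1 & pos <= len]
    S <- length(pos)
    freq <- sample.int(K - 1, S, replace = TRUE, prob = k_prob) / K
    # each haplotype draws independently from the shared site frequency
    hap <- matrix(stats::rbinom(n_hap * S, 1L, rep(freq, each = n_hap)),
                  nrow = n_hap, ncol = S)

    sw <- config$sweeps
    if (!is.null(sw) && nrow(sw) > 0) {
      for (si in which(sw$chrom == chr)) {
        lo <- sw$center[si] - sw$half_width[si]
        hi <- sw$center[si] + sw$half_width[si]
        in_sw <- which(pos - 1 >= lo & pos - 1 < hi)
        if (length(in_sw) == 0) next
        core <- stats::rbinom(length(in_sw), 1L, freq[in_sw])
        cf <- ifelse(hap_group == sw$selected_group[si],
                     sw$carrier_freq_selected[si],
                     sw$carrier_freq_other[si])
        carries <- stats::runif(n_hap) < cf
        for (h in which(carries)) {
          flip <- stats::runif(length(in_sw)) < sw$core_mutation_rate[si]
          hap[h, in_sw] <- ifelse(flip, 1L - core, core)
        }
      }
    }

    ref_alt <- draw_ref_alt(S)
    effect <- draw_effect_class(S, config$coding_fraction)
    sites_all[[chr]] <- tibble::tibble(chrom = chr, pos = pos,
                                       ref = ref_alt$ref,
                                       alt = ref_alt$alt,
                                       effect_class = effect)
    haps[[chr]] <- hap_matrix(hap, pos, chr, rep(samples, each = 2))
    dos <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
      hap[seq(2, n_hap, by = 2), , drop = FALSE]
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow = nrow(dos))
      dos[mask] <- NA_integer_
    }
    geno_cols[[chr]] <- dos
  }

  sites <- dplyr::bind_rows(sites_all)
  geno <- do.call(cbind, geno_cols)
  gm <- geno_matrix(geno, sites, samples, groups)

  truth <- if (is.null(config$sweeps) || nrow(config$sweeps) == 0) {
    tibble::tibble(chrom = character(0), start = numeric(0),
                   end = numeric(0), selected_group = character(0))
  } else {
    tibble::tibble(chrom = config$sweeps$chrom,
                   start = config$sweeps$center - config$sweeps$half_width,
                   end = config$sweeps$center + config$sweeps$half_width,
                   selected_group = config$sweeps$selected_group)
  }
  list(gm = gm, haps = haps, truth = truth, config = config)
}

# random ref/alt base pairs with a transition bias (ts:tv ~ 2.33, the
# mammalian genome-wide ballpark)
draw_ref_alt <- function(S, ts_prob = 0.7) {
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, S, replace = TRUE)
  is_ts <- stats::runif(S) < ts_prob
  alt <- character(S)
  alt[is_ts] <- ts_partner[ref[is_ts]]
  for (i in which(!is_ts)) {
    tv <- setdiff(bases, c(ref[i], ts_partner[ref[i]]))
    alt[i] <- sample(tv, 1)
  }
  list(ref = ref, alt = alt)
}

draw_effect_class <- function(S, coding_fraction) {
  eff <- rep(NA_character_, S)
  coding <- stats::runif(S) < coding_fraction
  eff[coding] <- sample(c("synonymous", "nonsynonymous", "stopgain",
                          "stoploss"),
                        sum(coding), replace = TRUE,
                        prob = c(0.60, 0.37, 0.02, 0.01))
  eff
}

#' Write a simulated dataset as a phased VCF (+ truth BED, group file)
#'
#' VCF 4.2 with phased GT fields built from the simulated haplotypes;
#' genotypes masked as missing in the genotype matrix are written `./.`.
#' The header carries contig lengths and the full simulation config as a
#' JSON provenance line. [read_vcf()] round-trips the genotype matrix
#' losslessly; [read_phased()] round-trips the haplotypes when no
#' missingness was injected.
#'
#' @param sim output of [simulate_sweep_data()].
#' @param path output VCF path.
#' @param truth_path optional BED path for the planted sweep intervals.
#' @param group_path optional two-column group TSV path.
#' @return `path`, invisibly.
#' @export
write_simulated_vcf <- function(sim, path, truth_path = NULL,
                                group_path = NULL) {
  gm <- sim$gm
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- sim$config
  cfg_json <- jsonlite::toJSON(
    list(n_per_group = cfg$n_per_group,
         chrom_specs = cfg$chrom_specs,
         snp_spacing = cfg$snp_spacing, sfs_shape = cfg$sfs_shape,
         sweeps = cfg$sweeps, missing_rate = cfg$missing_rate,
         coding_fraction = cfg$coding_fraction, seed = cfg$seed),
    auto_unbox = TRUE, digits = NA)
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", cfg$chrom_specs$name, ",length=",
           format(cfg$chrom_specs$length, scientific = FALSE,
                  trim = TRUE), ">"),
    paste0("##INFO=<ID=ANN_CLASS,Number=1,Type=String,",
           "Description=\"Functional effect class\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##sweepscan_sim_config=", cfg_json),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t")
  ), con)

  col_of <- split(seq_along(gm$sites$chrom), gm$sites$chrom)
  for (chr in names(sim$haps)) {
    hm <- sim$haps[[chr]]
    idx <- col_of[[chr]]
    geno <- gm$geno[, idx, drop = FALSE]
    n <- length(gm$samples)
    gt <- matrix("", nrow = length(idx), ncol = n)
    for (s in seq_len(n)) {
      gt[, s] <- paste0(hm$hap[2 * s - 1, ], "|", hm$hap[2 * s, ])
      gt[is.na(geno[s, ]), s] <- "./."
    }
    info <- ifelse(is.na(gm$sites$effect_class[idx]), ".",
                   paste0("ANN_CLASS=", gm$sites$effect_class[idx]))
    lines <- paste(chr,
                   format(gm$sites$pos[idx], scientific = FALSE,
                          trim = TRUE),
                   ".", gm$sites$ref[idx], gm$sites$alt[idx], ".", "PASS",
                   info, "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }

  if (!is.null(truth_path)) {
    readr::write_tsv(
      dplyr::mutate(sim$truth,
                    start = format(.data$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(.data$end, scientific = FALSE,
                                 trim = TRUE)),
      truth_path, col_names = FALSE)
  }
  if (!is.null(group_path)) {
    readr::write_tsv(tibble::tibble(sample = gm$samples,
                                    group = unname(gm$groups)),
                     group_path, col_names = FALSE)
  }
  invisible(path)
}
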