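#' Scan configuration
#'
#' Defaults are the scan design the package implements: 50 kb
#' non-overlapping windows for FST and XP-EHH, 10 kb windows for Hp,
#' Z(FST) > 5 and |XP-EHH| > 2 calling thresholds, Weir–Cockerham FST, at
#' least 10 SNPs per window.
#'
#' @param fst_window,hp_window,xpehh_window,tajima_window window sizes
#'   (bp).
#' @param fst_step,xpehh_step window steps (bp); equal to the size gives
#'   the non-overlapping partition.
#' @param zfst_threshold Z(FST) calling cut.
#' @param xpehh_threshold |XP-EHH| calling cut on window means.
#' @param estimator FST estimator, `"wc"` or `"hudson"`.
#' @param min_snps minimum SNPs per window.
#' @param ehh_cutoff EHH truncation threshold.
#' @param seed seed for any sampling steps (LD decay).
#' @return A `scan_config` list.
#' @export
scan_config <- function(fst_window = 50000, fst_step = fst_window,
                        hp_window = 10000, xpehh_window = 50000,
                        xpehh_step = xpehh_window, tajima_window = 50000,
                        zfst_threshold = 5, xpehh_threshold = 2,
                        estimator = c("wc", "hudson"), min_snps = 10,
                        ehh_cutoff = 0.05, seed = 1) {
  estimator <- match.arg(estimator)
  stopifnot(zfst_threshold > 0, xpehh_threshold > 0, fst_window >= 1000,
            hp_window >= 1000, xpehh_window >= 1000)
  structure(list(fst_window = fst_window, fst_step = fst_step,
                 hp_window = hp_window, xpehh_window = xpehh_window,
                 xpehh_step = xpehh_step, tajima_window = tajima_window,
                 zfst_threshold = zfst_threshold,
                 xpehh_threshold = xpehh_threshold, estimator = estimator,
                 min_snps = min_snps, ehh_cutoff = ehh_cutoff,
                 seed = seed),
            class = "scan_config")
}

#' Run the full two-group selective-sweep scan
#'
#' End to end: per-SNP FST, 50 kb window means, genome-wide
#' Z-transformation and Z(FST) calling; pooled iHH and XP-EHH from the
#' phased haplotypes, windowing and |XP-EHH| calling with the sign giving
#' the selected group; per-group pooled heterozygosity Hp and Tajima's D
#' tracks; gene intersection per method with union/intersection of the two
#' methods; ranked protein-altering variants; NJ trees from all SNPs and
#' from sweep-region SNPs. Deterministic given the inputs and config.
#'
#' @param gm a [geno_matrix()].
#' @param haps named list of [hap_matrix()] per chromosome (phased), or
#'   `NULL` to skip the XP-EHH arm.
#' @param config a [scan_config()].
#' @param annotation optional gene tibble from [read_genes()].
#' @param term_map optional term-to-gene map for [enrich()].
#' @param chrom_lengths optional named chromosome lengths; defaults to the
#'   maximum observed position.
#' @return A `sweep_scan` object (list of tracks, regions, gene sets,
#'   trees and a summary tibble) with [tidy()]/[glance()] methods.
#' @export
scan_sweeps <- function(gm, haps = NULL, config = scan_config(),
                        annotation = NULL, term_map = NULL,
                        chrom_lengths = NULL) {
  stopifnot(inherits(config, "scan_config"))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- implied_lengths(gm$sites$chrom, gm$sites$pos)
  }

  fst_sites <- fst_per_site(gm, estimator = config$estimator)
  fst_win <- window_mean(fst_sites, window_size = config$fst_window,
                         step = config$fst_step,
                         min_snps = config$min_snps,
                         chrom_lengths = chrom_lengths)
  zfst <- z_transform(fst_win)
  fst_regions <- call_regions(zfst, config$zfst_threshold, "greater",
                              method = "FST")

  xpehh_sites <- NULL
  xpehh_win <- NULL
  xpehh_regions <- tibble::tibble(chrom = character(0), start = numeric(0),
                                  end = numeric(0), method = character(0),
                                  direction = character(0),
                                  peak_value = numeric(0),
                                  member_windows = integer(0))
  if (!is.null(haps)) {
    hmA <- purrr::map(haps, subset_haplotypes,
                      samples = group_samples(gm, "A"))
    hmB <- purrr::map(haps, subset_haplotypes,
                      samples = group_samples(gm, "B"))
    xpehh_sites <- xpehh(hmA, hmB, cutoff = config$ehh_cutoff)
    xpehh_win <- window_xpehh(xpehh_sites,
                              window_size = config$xpehh_window,
                              step = config$xpehh_step,
                              min_snps = config$min_snps,
                              chrom_lengths = chrom_lengths)
    xpehh_regions <- call_regions(xpehh_win, config$xpehh_threshold,
                                  "abs_greater", method = "XPEHH")
  }

  hp_a <- pooled_heterozygosity(gm, "A", window_size = config$hp_window,
                                chrom_lengths = chrom_lengths)
  hp_b <- pooled_heterozygosity(gm, "B", window_size = config$hp_window,
                                chrom_lengths = chrom_lengths)
  td_a <- tajimas_d(gm, "A", window_size = config$tajima_window,
                    chrom_lengths = chrom_lengths)
  td_b <- tajimas_d(gm, "B", window_size = config$tajima_window,
                    chrom_lengths = chrom_lengths)

  regions <- dplyr::bind_rows(fst_regions, xpehh_regions)

  genes_fst <- genes_xp <- NULL
  combined <- NULL
  enrichment <- NULL
  ranked <- NULL
  if (!is.null(annotation)) {
    genes_fst <- genes_in_regions(fst_regions, annotation)
    genes_xp <- genes_in_regions(xpehh_regions, annotation)
    combined <- combine_methods(genes_fst, genes_xp)
    if (!is.null(term_map) && length(combined$union) > 0) {
      enrichment <- enrich(combined$union, unique(annotation$gene_id),
                           term_map)
    }
    if (nrow(regions) > 0) {
      ranked <- rank_coding_variants(gm, fst_sites, regions)
    }
  } else if (nrow(regions) > 0) {
    ranked <- rank_coding_variants(gm, fst_sites, regions)
  }

  tree_all <- neighbor_joining(pairwise_distance(gm))
  tree_sweep <- NULL
  if (nrow(regions) > 0) {
    idx <- sites_in_regions(gm, regions)
    if (length(idx) > 0) {
      tree_sweep <- neighbor_joining(pairwise_distance(gm, idx))
    }
  }

  summary <- regions |>
    dplyr::count(.data$method, .data$direction, name = "n_regions")

  structure(list(
    fst_sites = fst_sites, fst_windows = fst_win, zfst = zfst,
    xpehh_sites = xpehh_sites, xpehh_windows = xpehh_win,
    hp = list(A = hp_a, B = hp_b), tajima_d = list(A = td_a, B = td_b),
    regions = regions, genes = list(fst = genes_fst, xpehh = genes_xp,
                                    combined = combined),
    enrichment = enrichment, ranked_variants = ranked,
    trees = list(all_snps = tree_all, sweep_snps = tree_sweep),
    summary = summary, config = config, chrom_lengths = chrom_lengths
  ), class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("<sweep_scan>\n")
  cat("  FST regions:   ", sum(x$regions$method == "FST"), "\n")
  cat("  XP-EHH regions:", sum(x$regions$method == "XPEHH"),
      "(A:", sum(x$regions$method == "XPEHH" & x$regions$direction == "A"),
      " B:", sum(x$regions$method == "XPEHH" & x$regions$direction == "B"),
      ")\n")
  if (!is.null(x$genes$combined)) {
    cat("  genes: union", x$genes$combined$n_union, "/ shared",
        x$genes$combined$n_intersection, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sweep scan into its region table
#'
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return The region tibble (one row per called sweep region).
#' @exportS3Method generics::tidy
tidy.sweep_scan <- function(x, ...) x$regions

#' One-row summary of a sweep scan
#'
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return One-row tibble of region/gene counts and peak statistics.
#' @exportS3Method generics::glance
glance.sweep_scan <- function(x, ...) {
  tibble::tibble(
    n_fst_regions = sum(x$regions$method == "FST"),
    n_xpehh_regions = sum(x$regions$method == "XPEHH"),
    n_xpehh_regions_b = sum(x$regions$method == "XPEHH" &
                              x$regions$direction == "B"),
    max_zfst = if (all(is.na(x$zfst$value))) NA_real_
               else max(x$zfst$value, na.rm = TRUE),
    min_xpehh = if (is.null(x$xpehh_windows) ||
                    all(is.na(x$xpehh_windows$value))) NA_real_
                else min(x$xpehh_windows$value, na.rm = TRUE),
    n_genes_union = if (is.null(x$genes$combined)) NA_integer_
                    else x$genes$combined$n_union,
    n_genes_shared = if (is.null(x$genes$combined)) NA_integer_
                     else x$genes$combined$n_intersection
  )
}

#' Write the output bundle of a sweep scan to a directory
#'
#' Per-site FST TSV, windowed Z(FST)/XP-EHH/Hp/Tajima's D tracks, region
#' BEDs per method, gene lists, ranked variants, enrichment table, Newick
#' trees and a JSON summary with region counts per method and direction.
#'
#' @param scan a `sweep_scan` from [scan_sweeps()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  readr::write_tsv(scan$fst_sites, p("fst_per_site.tsv"))
  write_track(scan$zfst, p("zfst_windows.tsv"))
  if (!is.null(scan$xpehh_windows)) {
    write_track(scan$xpehh_windows, p("xpehh_windows.tsv"))
    readr::write_tsv(scan$xpehh_sites, p("xpehh_per_site.tsv"))
  }
  write_track(scan$hp$A, p("hp_A_windows.tsv"))
  write_track(scan$hp$B, p("hp_B_windows.tsv"))
  write_track(scan$tajima_d$A, p("tajima_d_A_windows.tsv"))
  write_track(scan$tajima_d$B, p("tajima_d_B_windows.tsv"))
  if (nrow(scan$regions) > 0) {
    readr::write_tsv(scan$regions, p("regions.tsv"))
    bed <- dplyr::mutate(scan$regions,
                         start = format(.data$start, scientific = FALSE,
                                        trim = TRUE),
                         end = format(.data$end, scientific = FALSE,
                                      trim = TRUE))
    readr::write_tsv(bed[, c("chrom", "start", "end", "method",
                             "direction", "peak_value")],
                     p("regions.bed"), col_names = FALSE)
  }
  if (!is.null(scan$genes$combined)) {
    writeLines(scan$genes$combined$union, p("genes_union.txt"))
    writeLines(scan$genes$combined$intersection, p("genes_shared.txt"))
  }
  if (!is.null(scan$ranked_variants)) {
    readr::write_tsv(scan$ranked_variants, p("ranked_variants.tsv"))
  }
  if (!is.null(scan$enrichment)) {
    readr::write_tsv(scan$enrichment, p("enrichment.tsv"))
  }
  writeLines(to_newick(scan$trees$all_snps), p("tree_all_snps.nwk"))
  if (!is.null(scan$trees$sweep_snps)) {
    writeLines(to_newick(scan$trees$sweep_snps), p("tree_sweep_snps.nwk"))
  }
  jsonlite::write_json(
    list(summary = scan$summary, glance = glance(scan),
         config = unclass(scan$config)),
    p("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the scan from files on disk
#'
#' Thin wrapper over [read_vcf()]/[read_phased()], [scan_sweeps()] and
#' [write_scan()].
#'
#' @param vcf_path multi-sample VCF (phased GT enables the XP-EHH arm).
#' @param group_path two-column sample/group TSV.
#' @param out_dir output directory.
#' @param annotation_path optional BED/GFF3 gene annotation.
#' @param config a [scan_config()].
#' @param phased whether GT fields are phased (enables XP-EHH).
#' @return The `sweep_scan` object, invisibly.
#' @export
run_scan <- function(vcf_path, group_path, out_dir,
                     annotation_path = NULL, config = scan_config(),
                     phased = TRUE) {
  groups <- read_group_file(group_path)
  gm <- read_vcf(vcf_path, groups)
  haps <- if (phased) read_phased(vcf_path, groups) else NULL
  annotation <- if (!is.null(annotation_path)) read_genes(annotation_path)
                else NULL
  scan <- scan_sweeps(gm, haps, config = config, annotation = annotation)
  write_scan(scan, out_dir)
  invisible(scan)
}

#' Cumulative genome coordinates for Manhattan plotting
#'
#' Adds a genome-wide cumulative position to a site or window track;
#' chromosome offsets advance by each chromosome's full length in the
#' order of `chrom_lengths`, so an empty chromosome still advances the
#' offset.
#'
#' @param track site track (`chrom`, `pos`, `value`) or window track
#'   (`chrom`, `start`, `end`, `value`); windows use their midpoint.
#' @param chrom_lengths named chromosome lengths in plotting order;
#'   defaults to the maximum observed coordinate per chromosome in track
#'   order.
#' @return Tibble `chrom`, `cumulative_pos`, `value`.
#' @export
manhattan_export <- function(track, chrom_lengths = NULL) {
  pos <- if ("pos" %in% names(track)) track$pos
         else (track$start + track$end) / 2
  if (is.null(chrom_lengths)) {
    lens <- tapply(if ("pos" %in% names(track)) track$pos else track$end,
                   track$chrom, max)
    chrom_lengths <- lens[unique(track$chrom)]
  }
  offsets <- stats::setNames(
    cumsum(c(0, utils::head(as.numeric(chrom_lengths), -1))),
    names(chrom_lengths))
  tibble::tibble(chrom = track$chrom,
                 cumulative_pos = pos + unname(offsets[track$chrom]),
                 value = track$value)
}
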