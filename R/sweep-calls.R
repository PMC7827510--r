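#' Call sweep regions from a thresholded window track
#'
#' Windows exceeding the rule (`value > threshold`, or
#' `|value| > threshold` for signed statistics such as windowed XP-EHH) are
#' merged into maximal runs of adjacent or overlapping windows on the same
#' chromosome carrying the same direction. Undefined windows break runs.
#' For unsigned statistics (Z(FST)) the direction is `"nondirectional"`;
#' for signed ones a positive window mean implicates group A, a negative
#' one group B, and a sign flip breaks the run.
#'
#' @param track window-track tibble (typically Z-transformed FST from
#'   [z_transform()] or windowed XP-EHH from [window_xpehh()]).
#' @param threshold calling threshold (e.g. 5 for Z(FST), 2 for XP-EHH).
#' @param mode `"greater"` or `"abs_greater"`.
#' @param method label stored on the regions (default from the track's
#'   statistic attribute).
#' @return Tibble of regions: `chrom`, `start`, `end` (0-based half-open),
#'   `method`, `direction`, `peak_value`, `member_windows`.
#' @export
call_regions <- function(track, threshold, mode = c("greater", "abs_greater"),
                         method = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  method <- method %||% track_stat(track) %||% "stat"
  sig <- !is.na(track$value) &
    (if (mode == "greater") track$value > threshold
     else abs(track$value) > threshold)
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), method = character(0),
                          direction = character(0), peak_value = numeric(0),
                          member_windows = integer(0))
  if (!any(sig)) return(empty)
  hits <- track[sig, , drop = FALSE]
  hits <- dplyr::arrange(hits, .data$chrom, .data$start)
  hits$direction <- if (mode == "greater") "nondirectional" else
    ifelse(hits$value > 0, "A", "B")

  out <- list()
  cur <- NULL
  flush <- function(cur) {
    tibble::tibble(chrom = cur$chrom, start = cur$start, end = cur$end,
                   method = method, direction = cur$direction,
                   peak_value = cur$peak, member_windows = cur$n)
  }
  for (i in seq_len(nrow(hits))) {
    w <- hits[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$start <= cur$end &&
        w$direction == cur$direction) {
      cur$end <- max(cur$end, w$end)
      cur$n <- cur$n + 1L
      if (abs(w$value) > abs(cur$peak)) cur$peak <- w$value
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end,
                  direction = w$direction, peak = w$value, n = 1L)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  dplyr::bind_rows(out)
}

#' Genes overlapping sweep regions
#'
#' A gene is reported iff its interval overlaps any region by at least 1 bp
#' under the half-open convention (abutting intervals do not overlap).
#' Genes hitting several regions are collapsed by `gene_id`.
#'
#' @param regions region tibble from [call_regions()].
#' @param annotation gene tibble from [read_genes()] (0-based half-open
#'   `start`/`end`).
#' @return Tibble of distinct overlapping genes, with the method(s) and
#'   direction(s) of the regions hit.
#' @export
genes_in_regions <- function(regions, annotation) {
  if (nrow(regions) > 0 && nrow(annotation) > 0 &&
      length(intersect(unique(regions$chrom),
                       unique(annotation$chrom))) == 0) {
    warning("no shared chromosome names between regions (",
            paste(unique(regions$chrom), collapse = ","),
            ") and annotation (",
            paste(unique(annotation$chrom), collapse = ","), ")",
            call. = FALSE)
  }
  hits <- dplyr::inner_join(annotation, regions, by = "chrom",
                            suffix = c("", ".region"),
                            relationship = "many-to-many")
  hits <- dplyr::filter(hits, .data$start < .data$end.region,
                        .data$end > .data$start.region)
  hits |>
    dplyr::group_by(.data$gene_id, .data$gene_name, .data$chrom,
                    .data$start, .data$end, .data$strand) |>
    dplyr::summarise(
      method = paste(sort(unique(.data$method)), collapse = ","),
      direction = paste(sort(unique(.data$direction)), collapse = ","),
      n_regions = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Combine the gene sets of two sweep-detection methods
#'
#' @param genes_fst,genes_xpehh character vectors of gene ids (or tibbles
#'   with a `gene_id` column).
#' @return List with `union`, `intersection` (sorted id vectors) and their
#'   sizes `n_union`, `n_intersection`.
#' @export
combine_methods <- function(genes_fst, genes_xpehh) {
  ids <- function(x) if (is.data.frame(x)) unique(x$gene_id) else unique(x)
  f <- ids(genes_fst); x <- ids(genes_xpehh)
  u <- sort(union(f, x)); i <- sort(intersect(f, x))
  list(union = u, intersection = i,
       n_union = length(u), n_intersection = length(i))
}

protein_altering_classes <- c("nonsynonymous", "stopgain", "stoploss",
                              "frameshift")

#' Rank protein-altering variants by single-site FST
#'
#' Protein-altering sites (nonsynonymous, stopgain, stoploss, frameshift by
#' their annotated effect class) falling inside the given regions or gene
#' intervals, sorted by descending single-site FST with ties broken by
#' (chrom, pos). Per-group alternate-allele frequencies are attached.
#'
#' @param gm a [geno_matrix()] whose sites carry `effect_class`.
#' @param fst_track per-site FST tibble from [fst_per_site()].
#' @param intervals tibble with `chrom`, `start`, `end` (0-based
#'   half-open): sweep regions or gene bodies.
#' @return Tibble of ranked variants with `fst`, `alt_freq_a`,
#'   `alt_freq_b`.
#' @export
rank_coding_variants <- function(gm, fst_track, intervals) {
  in_iv <- rep(FALSE, nrow(gm$sites))
  for (i in seq_len(nrow(intervals))) {
    in_iv <- in_iv | (gm$sites$chrom == intervals$chrom[i] &
                        gm$sites$pos - 1 >= intervals$start[i] &
                        gm$sites$pos - 1 < intervals$end[i])
  }
  keep <- in_iv & gm$sites$effect_class %in% protein_altering_classes
  afA <- allele_frequencies(gm, "A")
  afB <- allele_frequencies(gm, "B")
  out <- tibble::tibble(
    chrom = gm$sites$chrom[keep], pos = gm$sites$pos[keep],
    ref = gm$sites$ref[keep], alt = gm$sites$alt[keep],
    effect_class = gm$sites$effect_class[keep],
    fst = fst_track$value[keep],
    alt_freq_a = afA$alt_freq[keep], alt_freq_b = afB$alt_freq[keep]
  )
  dplyr::arrange(out, dplyr::desc(.data$fst), .data$chrom, .data$pos)
}

#' Over-representation enrichment with BH correction
#'
#' One-sided hypergeometric tail test of term over-representation in a
#' candidate gene set against a gene universe, with Benjamini–Hochberg
#' adjustment across terms. Term-to-gene maps are user-supplied (no
#' database is queried); term genes are intersected with the universe
#' first. An overlap of zero gives p = 1 under the tail convention
#' P(X >= 0) = 1.
#'
#' @param gene_set character vector of candidate gene ids (subset of
#'   `universe`).
#' @param universe character vector of all testable gene ids.
#' @param term_map named list of character vectors (term -> gene ids), or a
#'   two-column data frame `term`, `gene_id`.
#' @return Tibble with `term`, `n_term`, `n_overlap`, `p`, `p_adj`, sorted
#'   by `p`.
#' @export
enrich <- function(gene_set, universe, term_map) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  gene_set <- intersect(unique(gene_set), universe)
  if (is.data.frame(term_map)) {
    term_map <- split(term_map$gene_id, term_map$term)
  }
  N <- length(universe)
  n <- length(gene_set)
  rows <- purrr::imap_dfr(term_map, function(genes, term) {
    K <- length(intersect(unique(genes), universe))
    k <- length(intersect(unique(genes), gene_set))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term, n_term = K, n_overlap = k, p = p)
  })
  rows$p_adj <- stats::p.adjust(rows$p, method = "BH")
  dplyr::arrange(rows, .data$p)
}

#' Compare genotype-class distributions between the two groups
#'
#' Tests whether genotype counts (e.g. +/+, +/-, -/- at a candidate
#' mutation) differ between the groups. Default is Fisher's exact test
#' (two-sided, appropriate at the small sample sizes of a resequencing
#' panel); Pearson's chi-square is selectable.
#'
#' @param counts 2 x k integer matrix (rows = groups, columns = genotype
#'   classes, k = 2 or 3).
#' @param method `"fisher"` or `"chisq"`.
#' @return Two-sided p-value.
#' @export
genotype_distribution_test <- function(counts, method = c("fisher",
                                                          "chisq")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || !ncol(counts) %in% c(2, 3)) {
    stop("counts must be a 2 x 2 or 2 x 3 table", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("every row and column margin must be positive", call. = FALSE)
  }
  if (method == "fisher") {
    stats::fisher.test(counts)$p.value
  } else {
    stats::chisq.test(counts, correct = FALSE)$p.value
  }
}
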