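#' Genotype matrix for a two-group sample design
#'
#' A `geno_matrix` bundles a samples-by-sites alternate-allele dosage matrix
#' (values 0, 1, 2 or `NA` for missing) with a site table and a two-group
#' sample partition. Group `"A"` is the control-like group (monotocous analog
#' in the sheep fecundity design this package targets), group `"B"` the
#' contrast group (polytocous analog). All per-site and windowed statistics
#' in the package consume this object and return tibbles.
#'
#' @param geno integer matrix, samples in rows, sites in columns; entries in
#'   `{0, 1, 2, NA}` (alternate-allele dosage).
#' @param sites tibble with columns `chrom`, `pos` (1-based bp), `ref`, `alt`
#'   and optionally `effect_class`; must be sorted by (`chrom`, `pos`) with
#'   strictly increasing `pos` within each chromosome.
#' @param samples character vector of sample identifiers, one per row of
#'   `geno`.
#' @param groups named character vector mapping every sample to `"A"` or
#'   `"B"`; both groups must be non-empty.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sites, samples, groups) {
  geno <- as.matrix(geno)
  sites <- tibble::as_tibble(sites)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    stop("`sites` needs columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (!"effect_class" %in% names(sites)) sites$effect_class <- NA_character_
  if (nrow(geno) != length(samples)) {
    stop("row count of `geno` must equal length(samples)", call. = FALSE)
  }
  if (ncol(geno) != nrow(sites)) {
    stop("column count of `geno` must equal nrow(sites)", call. = FALSE)
  }
  if (!all(samples %in% names(groups))) {
    missing <- setdiff(samples, names(groups))
    stop("samples without a group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- groups[samples]
  if (!all(groups %in% c("A", "B"))) {
    stop("groups must be 'A' or 'B'", call. = FALSE)
  }
  if (!all(c("A", "B") %in% groups)) {
    stop("both groups A and B must be non-empty", call. = FALSE)
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  ord_ok <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L) |>
    dplyr::pull(.data$ok)
  if (!all(ord_ok)) {
    stop("site positions must be strictly increasing within chromosome",
         call. = FALSE)
  }
  rownames(geno) <- samples
  structure(
    list(geno = geno, sites = sites, samples = samples, groups = groups),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$samples), " samples x ", nrow(x$sites),
      " sites on ", length(unique(x$sites$chrom)), " chromosome(s)\n",
      sep = "")
  cat("  groups: A=", sum(x$groups == "A"), " B=", sum(x$groups == "B"),
      "; missing calls: ", sum(is.na(x$geno)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Samples belonging to one group
#'
#' @param gm a [geno_matrix()].
#' @param group `"A"`, `"B"` or `"all"`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(gm, group = c("all", "A", "B")) {
  group <- match.arg(group)
  if (group == "all") gm$samples else gm$samples[gm$groups == group]
}

#' Phased haplotype matrix for one chromosome
#'
#' Two binary haplotypes per sample over the ordered sites of a single
#' chromosome. Phased input must be complete: no missing alleles are
#' accepted (phasing/imputation is upstream of this package).
#'
#' @param hap integer matrix of 0/1 alleles, haplotypes in rows (2 per
#'   sample, sample order preserved), sites in columns.
#' @param positions strictly increasing 1-based bp positions, one per column.
#' @param chrom chromosome name.
#' @param sample_of character vector mapping each haplotype row to its
#'   sample id.
#'
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(hap, positions, chrom, sample_of) {
  hap <- as.matrix(hap)
  if (anyNA(hap)) stop("phased haplotypes may not contain missing alleles",
                       call. = FALSE)
  if (!all(hap %in% c(0L, 1L))) stop("haplotype alleles must be 0/1",
                                     call. = FALSE)
  if (nrow(hap) %% 2L != 0L) stop("haplotype count must be even",
                                  call. = FALSE)
  if (length(positions) != ncol(hap)) {
    stop("one position per haplotype column required", call. = FALSE)
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (length(sample_of) != nrow(hap)) {
    stop("one sample id per haplotype row required", call. = FALSE)
  }
  structure(
    list(hap = hap, positions = as.numeric(positions),
         chrom = as.character(chrom), sample_of = as.character(sample_of)),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", nrow(x$hap), " haplotypes x ", ncol(x$hap),
      " sites on ", x$chrom, "\n", sep = "")
  invisible(x)
}

#' Restrict a haplotype matrix to the haplotypes of selected samples
#'
#' @param hm a [hap_matrix()].
#' @param samples sample ids to keep.
#' @return A `hap_matrix` over the same sites.
#' @export
subset_haplotypes <- function(hm, samples) {
  keep <- hm$sample_of %in% samples
  if (!any(keep)) stop("no haplotypes left after subsetting", call. = FALSE)
  hap_matrix(hm$hap[keep, , drop = FALSE], hm$positions, hm$chrom,
             hm$sample_of[keep])
}
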