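#' Extended haplotype homozygosity decay from a core site
#'
#' Classical EHH: among the haplotypes carrying `allele` at the core site,
#' EHH at marker x is the probability that two randomly drawn carriers are
#' identical over the whole segment from the core to x,
#' `EHH(x) = sum_h C(|class h|, 2) / C(n_carriers, 2)`. The curve starts at
#' 1 at the core and is non-increasing outward; extension stops when EHH
#' drops below `cutoff` or the chromosome end is reached (that marker is
#' included).
#'
#' @param hm a [hap_matrix()].
#' @param core_index 1-based site index of the core.
#' @param allele core allele, 0 or 1.
#' @param direction `"right"` or `"left"`.
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return Tibble with columns `pos`, `offset` (bp from core, signed) and
#'   `ehh`; attribute `n_carriers`. Zero rows (and attribute
#'   `undefined = TRUE`) when fewer than two carriers exist.
#' @export
ehh <- function(hm, core_index, allele, direction = c("right", "left"),
                cutoff = 0.05) {
  direction <- match.arg(direction)
  if (core_index < 1 || core_index > ncol(hm$hap)) {
    stop("core index out of range", call. = FALSE)
  }
  res <- .ehh_side_cpp(hm$hap, core_index - 1L, as.integer(allele),
                       direction == "right", cutoff)
  if (res$n_carriers < 2) {
    out <- tibble::tibble(pos = numeric(0), offset = numeric(0),
                          ehh = numeric(0))
    attr(out, "undefined") <- TRUE
    attr(out, "n_carriers") <- res$n_carriers
    return(out)
  }
  pos <- hm$positions[res$markers + 1L]
  out <- tibble::tibble(pos = pos,
                        offset = pos - hm$positions[core_index],
                        ehh = res$ehh)
  attr(out, "n_carriers") <- res$n_carriers
  out
}

#' Integrated haplotype homozygosity (iHH) at a core site
#'
#' Trapezoidal integral of the EHH curve against physical distance (bp),
#' summed over the left and right directions. The integral is truncated at
#' the first marker where EHH falls below `cutoff` (included as the final
#' trapezoid endpoint) or at the chromosome end.
#'
#' @inheritParams ehh
#' @param allele core allele 0 or 1, or `NULL` for the pooled
#'   (allele-agnostic) convention used by XP-EHH.
#' @return iHH in bp, or `NA` when the curve is undefined.
#' @export
ihh <- function(hm, core_index, allele = NULL, cutoff = 0.05) {
  if (core_index < 1 || core_index > ncol(hm$hap)) {
    stop("core index out of range", call. = FALSE)
  }
  a <- if (is.null(allele)) -1L else as.integer(allele)
  .ihh_cpp(hm$hap, hm$positions, core_index - 1L, a, cutoff)
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' For each site, the pooled iHH (all haplotypes of the group, both core
#' alleles) is computed in each group and the raw score is
#' `ln(iHH_A / iHH_B)`; positive values indicate unusually long haplotypes
#' — a selection signal — in group A, negative values in group B. Raw
#' scores are then standardized genome-wide (one pass, unbinned) so that a
#' fixed cut such as |XP-EHH| > 2 marks outliers. Sites where either
#' group's iHH is zero or undefined are flagged `NA`.
#'
#' @param hmA,hmB [hap_matrix()] objects over identical site lists, or
#'   named lists of them (one per chromosome, matching names).
#' @param cutoff EHH truncation threshold passed to the iHH kernel.
#' @return Tibble with columns `chrom`, `pos`, `ihh_a`, `ihh_b`, `raw`,
#'   `value` (normalized score); attributes `genomewide_mean`,
#'   `genomewide_sd`.
#' @export
xpehh <- function(hmA, hmB, cutoff = 0.05) {
  if (inherits(hmA, "hap_matrix")) hmA <- list(hmA)
  if (inherits(hmB, "hap_matrix")) hmB <- list(hmB)
  if (length(hmA) != length(hmB)) {
    stop("group A and B must cover the same chromosomes", call. = FALSE)
  }
  per_chrom <- purrr::map2_dfr(hmA, hmB, function(a, b) {
    if (!identical(a$positions, b$positions) ||
        !identical(a$chrom, b$chrom)) {
      stop("haplotype matrices must share one site list", call. = FALSE)
    }
    m <- .ihh_scan_cpp(a$hap, b$hap, a$positions, cutoff)
    tibble::tibble(chrom = a$chrom, pos = a$positions,
                   ihh_a = m[, 1], ihh_b = m[, 2])
  })
  # log difference (not log of the quotient) so that swapping the groups
  # negates every raw score bit-exactly
  raw <- ifelse(!is.na(per_chrom$ihh_a) & !is.na(per_chrom$ihh_b) &
                  per_chrom$ihh_a > 0 & per_chrom$ihh_b > 0,
                log(per_chrom$ihh_a) - log(per_chrom$ihh_b), NA_real_)
  def <- raw[!is.na(raw)]
  if (length(def) < 2) stop("too few defined XP-EHH sites to normalize",
                            call. = FALSE)
  m <- mean(def)
  s <- stats::sd(def)
  if (s == 0) {
    warning("degenerate XP-EHH distribution (zero sd); ",
            "normalized scores set to NA", call. = FALSE)
    out <- dplyr::mutate(per_chrom, raw = raw, value = NA_real_)
  } else {
    out <- dplyr::mutate(per_chrom, raw = raw, value = (raw - m) / s)
  }
  attr(out, "genomewide_mean") <- m
  attr(out, "genomewide_sd") <- if (s == 0) NA_real_ else s
  set_track_stat(out, "xpehh")
}

#' Average normalized XP-EHH scores over genomic windows
#'
#' Window means of the already-normalized per-site scores; the fixed
#' |XP-EHH| > 2 calling rule is applied to these window means (no
#' re-standardization). Defaults: 50 kb non-overlapping windows, at least
#' 10 SNPs.
#'
#' @param track tibble from [xpehh()].
#' @inheritParams window_mean
#' @return Window-track tibble.
#' @export
window_xpehh <- function(track, window_size = 50000, step = window_size,
                         min_snps = 10, chrom_lengths = NULL) {
  site_track <- tibble::tibble(chrom = track$chrom, pos = track$pos,
                               value = track$value)
  site_track <- set_track_stat(site_track, "xpehh")
  window_mean(site_track, window_size = window_size, step = step,
              min_snps = min_snps, chrom_lengths = chrom_lengths)
}

#' Trapezoidal integral of a one-sided EHH curve
#'
#' Integrates an EHH decay curve against physical distance:
#' `sum_k |offset_k - offset_(k-1)| * (ehh_k + ehh_(k-1)) / 2`. [ihh()] is
#' exactly the sum of this integral over the left and right curves.
#'
#' @param curve tibble with `offset` (bp) and `ehh` columns, ordered
#'   outward from the core (as returned by [ehh()]).
#' @return Area in bp.
#' @export
integrate_ehh <- function(curve) {
  if (nrow(curve) < 2) return(0)
  sum(abs(diff(curve$offset)) *
        (utils::head(curve$ehh, -1) + utils::tail(curve$ehh, -1)) / 2)
}

# haplotype-count LD for one site pair: r2 and D'
ld_pair <- function(hap, i, j) {
  pA <- mean(hap[, i])
  pB <- mean(hap[, j])
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(c(r2 = NA_real_, dprime = NA_real_))
  }
  pAB <- mean(hap[, i] == 1L & hap[, j] == 1L)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), pB * (1 - pA))
          else min(pA * pB, (1 - pA) * (1 - pB))
  c(r2 = r2, dprime = if (dmax == 0) NA_real_ else abs(D) / dmax)
}

#' Linkage disequilibrium r-squared between two sites
#'
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))` from phased
#' haplotype counts. Undefined (`NA`) when either site is monomorphic among
#' the haplotypes.
#'
#' @param hm a [hap_matrix()].
#' @param site_i,site_j 1-based site indices.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(hm, site_i, site_j) {
  unname(ld_pair(hm$hap, site_i, site_j)["r2"])
}

#' Mean LD decay across physical distance bins
#'
#' Randomly samples up to `n_snps_sample` sites passing the MAF filter
#' (phased input has no missing alleles, so `max_missing` is accepted for
#' interface parity but has no effect), computes r-squared and D' for all
#' intra-chromosome pairs closer than the largest bin edge, and reports the
#' mean per left-closed right-open distance bin.
#'
#' @param hm a [hap_matrix()] or list of them.
#' @param n_snps_sample maximum number of sites to sample.
#' @param max_missing accepted for interface parity; phased haplotypes are
#'   complete.
#' @param min_maf minimum minor allele frequency among haplotypes.
#' @param distance_bins ordered bp bin edges, first edge 0.
#' @param seed RNG seed for the site sample.
#' @return Tibble with `bin_start`, `bin_end`, `n_pairs`, `mean_r2`,
#'   `mean_dprime`.
#' @export
ld_decay <- function(hm, n_snps_sample = 5000, max_missing = 0.2,
                     min_maf = 0.1,
                     distance_bins = c(0, 1e3, 2e3, 5e3, 1e4, 2e4, 5e4),
                     seed = 1) {
  stopifnot(distance_bins[1] == 0, !is.unsorted(distance_bins))
  if (inherits(hm, "hap_matrix")) hm <- list(hm)
  max_dist <- distance_bins[length(distance_bins)]
  n_bins <- length(distance_bins) - 1

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  sums_r2 <- numeric(n_bins)
  sums_dp <- numeric(n_bins)
  n_dp <- integer(n_bins)
  counts <- integer(n_bins)
  for (h in hm) {
    freqs <- colMeans(h$hap)
    maf <- pmin(freqs, 1 - freqs)
    eligible <- which(maf >= min_maf & maf > 0)
    if (length(eligible) < 2) next
    take <- if (length(eligible) > n_snps_sample)
      sort(sample(eligible, n_snps_sample)) else eligible
    pos <- h$positions[take]
    # restrict to pairs within the largest bin edge
    for (ii in seq_along(take)) {
      jj <- ii + 1L
      while (jj <= length(take) && pos[jj] - pos[ii] < max_dist) {
        st <- ld_pair(h$hap, take[ii], take[jj])
        b <- findInterval(pos[jj] - pos[ii], distance_bins)
        if (b >= 1 && b <= n_bins && !is.na(st["r2"])) {
          sums_r2[b] <- sums_r2[b] + st["r2"]
          counts[b] <- counts[b] + 1L
          if (!is.na(st["dprime"])) {
            sums_dp[b] <- sums_dp[b] + st["dprime"]
            n_dp[b] <- n_dp[b] + 1L
          }
        }
        jj <- jj + 1L
      }
    }
  }
  tibble::tibble(
    bin_start = distance_bins[-length(distance_bins)],
    bin_end = distance_bins[-1],
    n_pairs = counts,
    mean_r2 = ifelse(counts > 0, sums_r2 / counts, NA_real_),
    mean_dprime = ifelse(n_dp > 0, sums_dp / n_dp, NA_real_)
  )
}
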