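#' Per-site allele frequencies
#'
#' Frequencies are computed over non-missing calls only; a site with zero
#' called genotypes in the chosen group is flagged undefined (`NA`), never
#' silently zero.
#'
#' @param gm a [geno_matrix()].
#' @param group `"A"`, `"B"` or `"all"`.
#' @return Tibble with columns `chrom`, `pos`, `n_called`, `alt_freq`,
#'   `maf`.
#' @export
allele_frequencies <- function(gm, group = c("all", "A", "B")) {
  group <- match.arg(group)
  g <- gm$geno[group_samples(gm, group), , drop = FALSE]
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE) / (2 * n_called)
  alt[n_called == 0] <- NA_real_
  tibble::tibble(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    n_called = as.integer(n_called),
    alt_freq = alt, maf = pmin(alt, 1 - alt)
  )
}

#' Minor allele frequency spectrum
#'
#' Histogram of per-site MAF over `[0, 0.5]`, left-closed right-open bins
#' (the last bin closed). Sites with undefined MAF are excluded; counts sum
#' to the number of defined sites.
#'
#' @inheritParams allele_frequencies
#' @param n_bins number of equal-width bins over `[0, 0.5]`.
#' @return Tibble with `bin_start`, `bin_end`, `count`.
#' @export
maf_spectrum <- function(gm, group = c("all", "A", "B"), n_bins = 20) {
  group <- match.arg(group)
  stopifnot(n_bins >= 1)
  maf <- allele_frequencies(gm, group)$maf
  maf <- maf[!is.na(maf)]
  edges <- seq(0, 0.5, length.out = n_bins + 1)
  idx <- pmin(findInterval(maf, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(bin_start = edges[-(n_bins + 1)], bin_end = edges[-1],
                 count = counts)
}

#' Heterozygosity rate of a group
#'
#' Fraction of non-missing genotype calls that are heterozygous, pooled over
#' all sites and samples of the group.
#'
#' @inheritParams allele_frequencies
#' @return A single fraction, or `NA` when no calls exist.
#' @export
heterozygosity_rate <- function(gm, group = c("all", "A", "B")) {
  group <- match.arg(group)
  g <- gm$geno[group_samples(gm, group), , drop = FALSE]
  n_called <- sum(!is.na(g))
  if (n_called == 0) return(NA_real_)
  sum(g == 1L, na.rm = TRUE) / n_called
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; every other REF/ALT pair is a
#' transversion. Only sites polymorphic in the chosen group are counted.
#' Returns `NA` when there are no transversions.
#'
#' @inheritParams allele_frequencies
#' @return ts/tv ratio.
#' @export
ts_tv_ratio <- function(gm, group = c("all", "A", "B")) {
  group <- match.arg(group)
  af <- allele_frequencies(gm, group)
  poly <- !is.na(af$maf) & af$maf > 0
  pair <- paste0(pmin(gm$sites$ref, gm$sites$alt),
                 pmax(gm$sites$ref, gm$sites$alt))[poly]
  is_ts <- pair %in% c("AG", "CT")
  n_tv <- sum(!is_ts)
  if (n_tv == 0) return(NA_real_)
  sum(is_ts) / n_tv
}

#' Per-SNP FST between the two groups
#'
#' The default estimator is the Weir–Cockerham (1984) two-population
#' variance-components estimator `theta = a / (a + b + c)`, computed from
#' group sample sizes, allele frequencies and observed heterozygote
#' frequencies — the canonical small-sample-corrected estimator. A
#' Hudson-type estimator with the Bhatia et al. small-sample correction is
#' selectable. Negative estimates are retained as computed (clamping would
#' bias window means upward). Sites where either group has fewer than two
#' called genotypes are flagged undefined; sites monomorphic in both groups
#' take the value 0 (the variance components are degenerate there).
#'
#' @param gm a [geno_matrix()].
#' @param estimator `"wc"` (Weir–Cockerham 1984) or `"hudson"` (Bhatia
#'   small-sample-corrected).
#' @return Site-track tibble with columns `chrom`, `pos`, `value`; the
#'   `statistic` attribute records the estimator.
#' @export
fst_per_site <- function(gm, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  gA <- gm$geno[group_samples(gm, "A"), , drop = FALSE]
  gB <- gm$geno[group_samples(gm, "B"), , drop = FALSE]
  nA <- colSums(!is.na(gA))
  nB <- colSums(!is.na(gB))
  pA <- colSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(gB, na.rm = TRUE) / (2 * nB)
  ok <- nA >= 2 & nB >= 2

  if (estimator == "wc") {
    hA <- colSums(gA == 1L, na.rm = TRUE) / nA
    hB <- colSums(gB == 1L, na.rm = TRUE) / nB
    r <- 2
    nbar <- (nA + nB) / r
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    denom <- a + b + cc
    val <- ifelse(denom == 0, 0, a / denom)
  } else {
    # Hudson estimator, sample-size-corrected numerator; n in allele copies
    mA <- 2 * nA
    mB <- 2 * nB
    num <- (pA - pB)^2 -
      pA * (1 - pA) / (mA - 1) - pB * (1 - pB) / (mB - 1)
    den <- pA * (1 - pB) + pB * (1 - pA)
    val <- ifelse(den == 0, 0, num / den)
  }
  val[!ok] <- NA_real_
  out <- tibble::tibble(chrom = gm$sites$chrom, pos = gm$sites$pos,
                        value = val)
  set_track_stat(out, paste0("fst_", estimator))
}

#' Genomic windows for a set of chromosomes
#'
#' 0-based half-open fixed-size windows; the terminal window is truncated to
#' the chromosome length.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window size in bp.
#' @param step step in bp (`step = window_size` gives the non-overlapping
#'   partition).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
genome_windows <- function(chrom_lengths, window_size, step = window_size) {
  stopifnot(window_size >= step, step >= 1)
  purrr::imap_dfr(chrom_lengths, function(len, chr) {
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    tibble::tibble(chrom = chr, start = starts,
                   end = pmin(starts + window_size, len))
  })
}

# chromosome lengths implied by a site track when none are supplied
implied_lengths <- function(chrom, pos) {
  tapply(pos, chrom, max)
}

#' Average a per-site statistic over genomic windows
#'
#' The window value is the arithmetic mean of the defined site values whose
#' position falls in `[start, end)`. Windows holding fewer than `min_snps`
#' defined sites are flagged undefined (`NA`) and are excluded from any
#' downstream normalization. Defaults follow the scan design: 50 kb
#' non-overlapping windows, at least 10 SNPs.
#'
#' @param track site-track tibble (`chrom`, `pos`, `value`), e.g. from
#'   [fst_per_site()].
#' @param window_size window size in bp.
#' @param step step in bp.
#' @param min_snps minimum defined SNPs per window.
#' @param chrom_lengths optional named chromosome lengths; defaults to the
#'   maximum observed position per chromosome.
#' @return Window-track tibble `chrom`, `start`, `end`, `n_snps`, `value`.
#' @export
window_mean <- function(track, window_size = 50000, step = window_size,
                        min_snps = 10, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- implied_lengths(track$chrom, track$pos)
  }
  win <- genome_windows(chrom_lengths, window_size, step)
  res <- purrr::pmap_dfr(win, function(chrom, start, end) {
    sel <- track$chrom == chrom & track$pos - 1 >= start &
      track$pos - 1 < end & !is.na(track$value)
    n <- sum(sel)
    tibble::tibble(chrom = chrom, start = start, end = end,
                   n_snps = as.integer(n),
                   value = if (n >= min_snps) mean(track$value[sel])
                           else NA_real_)
  })
  set_track_stat(res, paste0("win_", track_stat(track) %||% "stat"))
}

#' Z-transform a window track genome-wide
#'
#' Standardizes defined window values with the genome-wide mean and sample
#' standard deviation (all chromosomes pooled) and stores both constants on
#' the track. Outlier windows are then callable by a fixed cut such as
#' Z(FST) > 5.
#'
#' @param track a window-track tibble.
#' @return The track with standardized `value` and attributes
#'   `genomewide_mean`, `genomewide_sd`.
#' @export
z_transform <- function(track) {
  v <- track$value[!is.na(track$value)]
  if (length(v) < 2) stop("need at least two defined windows", call. = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) stop("degenerate track: zero genome-wide standard deviation",
                   call. = FALSE)
  out <- track
  out$value <- (track$value - m) / s
  attr(out, "genomewide_mean") <- m
  attr(out, "genomewide_sd") <- s
  set_track_stat(out, paste0("z_", track_stat(track) %||% "stat"))
}

#' Pooled heterozygosity Hp in genomic windows
#'
#' For each window, major and minor allele counts are summed over the SNPs
#' of the chosen group (counts over non-missing calls; the major allele is
#' resolved per site within the group, exact ties assigning REF as major)
#' and
#' \deqn{Hp = 2 \Sigma n_{MAJ} \Sigma n_{MIN} /
#'   (\Sigma n_{MAJ} + \Sigma n_{MIN})^2.}
#' Hp lies in `[0, 0.5]` and is depressed where a sweep has removed
#' variation. Windows with no called alleles are undefined.
#'
#' @inheritParams allele_frequencies
#' @param window_size window size in bp (default 10 kb).
#' @param chrom_lengths optional named chromosome lengths.
#' @return Window-track tibble.
#' @export
pooled_heterozygosity <- function(gm, group = c("all", "A", "B"),
                                  window_size = 10000,
                                  chrom_lengths = NULL) {
  group <- match.arg(group)
  g <- gm$geno[group_samples(gm, group), , drop = FALSE]
  n_called <- colSums(!is.na(g))
  alt_count <- colSums(g, na.rm = TRUE)
  ref_count <- 2 * n_called - alt_count
  maj <- ifelse(alt_count > ref_count, alt_count, ref_count)  # tie -> ref
  minr <- ifelse(alt_count > ref_count, ref_count, alt_count)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- implied_lengths(gm$sites$chrom, gm$sites$pos)
  }
  win <- genome_windows(chrom_lengths, window_size, window_size)
  res <- purrr::pmap_dfr(win, function(chrom, start, end) {
    sel <- gm$sites$chrom == chrom & gm$sites$pos - 1 >= start &
      gm$sites$pos - 1 < end & n_called > 0
    smaj <- sum(maj[sel]); smin <- sum(minr[sel])
    tot <- smaj + smin
    tibble::tibble(chrom = chrom, start = start, end = end,
                   n_snps = as.integer(sum(sel)),
                   value = if (tot > 0) 2 * smaj * smin / tot^2 else NA_real_)
  })
  set_track_stat(res, paste0("hp_", group))
}

#' Tajima's D in genomic windows
#'
#' Standard Tajima (1989) statistic per window:
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the a1/a2/b1/b2/c1/c2/
#' e1/e2 constants computed from the number of allele copies. Pairwise
#' diversity pi uses per-site called-copy counts
#' (`2*j*(n-j)/(n*(n-1))` per site); the constants use the window median of
#' the called-copy counts, a VCFtools-like treatment of missingness.
#' Windows with no segregating sites are undefined.
#'
#' @inheritParams allele_frequencies
#' @param window_size window size in bp (default 50 kb).
#' @param chrom_lengths optional named chromosome lengths.
#' @return Window-track tibble (`n_snps` counts segregating sites).
#' @export
tajimas_d <- function(gm, group = c("all", "A", "B"), window_size = 50000,
                      chrom_lengths = NULL) {
  group <- match.arg(group)
  g <- gm$geno[group_samples(gm, group), , drop = FALSE]
  n_copies <- 2 * colSums(!is.na(g))
  j <- colSums(g, na.rm = TRUE)
  seg <- n_copies >= 2 & j > 0 & j < n_copies
  pi_site <- ifelse(seg, 2 * j * (n_copies - j) /
                      (n_copies * (n_copies - 1)), 0)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- implied_lengths(gm$sites$chrom, gm$sites$pos)
  }
  win <- genome_windows(chrom_lengths, window_size, window_size)
  res <- purrr::pmap_dfr(win, function(chrom, start, end) {
    sel <- gm$sites$chrom == chrom & gm$sites$pos - 1 >= start &
      gm$sites$pos - 1 < end
    S <- sum(seg[sel])
    if (S == 0) {
      return(tibble::tibble(chrom = chrom, start = start, end = end,
                            n_snps = 0L, value = NA_real_))
    }
    n <- stats::median(n_copies[sel & seg])
    tibble::tibble(chrom = chrom, start = start, end = end,
                   n_snps = as.integer(S),
                   value = tajima_d_stat(sum(pi_site[sel]), S, n))
  })
  set_track_stat(res, paste0("tajima_d_", group))
}

# Tajima (1989) normalization given pi, S, and n allele copies
tajima_d_stat <- function(pi, S, n) {
  if (n < 2 || S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi - S / a1) / denom
}
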