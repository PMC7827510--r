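# Independent second transcriptions of the reference formulas, written as
# explicit loops/sums so they share no code with the package internals.

# Weir & Cockerham (1984) two-population theta at one site, from dosage
# vectors (0/1/2/NA) of the two groups. Explicit sums over populations.
wc_theta_oracle <- function(dosA, dosB) {
  pops <- list(dosA[!is.na(dosA)], dosB[!is.na(dosB)])
  r <- 2
  n <- vapply(pops, length, numeric(1))
  if (any(n < 2)) return(NA_real_)
  p <- vapply(pops, function(d) sum(d) / (2 * length(d)), numeric(1))
  h <- vapply(pops, function(d) mean(d == 1), numeric(1))
  nbar <- mean(n)
  sum_n2 <- 0
  for (i in 1:r) sum_n2 <- sum_n2 + n[i]^2
  nc <- (r * nbar - sum_n2 / (r * nbar)) / (r - 1)
  pbar <- 0
  for (i in 1:r) pbar <- pbar + n[i] * p[i]
  pbar <- pbar / (r * nbar)
  s2 <- 0
  for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2
  s2 <- s2 / ((r - 1) * nbar)
  hbar <- 0
  for (i in 1:r) hbar <- hbar + n[i] * h[i]
  hbar <- hbar / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                           hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(0)
  a / (a + b + cc)
}

# Tajima (1989) D from per-site derived-allele counts j over n copies.
tajima_oracle <- function(j, n) {
  seg <- j > 0 & j < n
  S <- sum(seg)
  if (S == 0 || n < 2) return(NA_real_)
  pi <- 0
  for (jj in j[seg]) pi <- pi + 2 * jj * (n - jj) / (n * (n - 1))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# EHH by exhaustive pair enumeration: for each marker outward from the
# core, count haplotype pairs identical over the whole core..marker
# segment. Mirrors the truncation rule (stop after first EHH < cutoff).
ehh_oracle <- function(hap, core, allele, direction, cutoff = 0.05) {
  carriers <- if (is.null(allele)) seq_len(nrow(hap)) else
    which(hap[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NULL)
  markers <- core
  ehh <- 1
  step <- if (direction == "right") 1L else -1L
  m <- core + step
  while (m >= 1 && m <= ncol(hap)) {
    # allele-specific: segment spans core..m (the core is a no-op split
    # among carriers); pooled/allele-agnostic: the core allele is ignored
    seg <- if (is.null(allele)) {
      if (direction == "right") (core + 1):m else m:(core - 1)
    } else {
      if (direction == "right") core:m else m:core
    }
    same <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (all(hap[carriers[i], seg] == hap[carriers[j], seg])) {
          same <- same + 1
        }
      }
    }
    e <- same / (n * (n - 1) / 2)
    markers <- c(markers, m)
    ehh <- c(ehh, e)
    if (e < cutoff) break
    m <- m + step
  }
  list(markers = markers, ehh = ehh, n_carriers = n)
}

# iHH from the oracle EHH curves: trapezoid against bp, left + right.
ihh_oracle <- function(hap, positions, core, allele, cutoff = 0.05) {
  total <- 0
  for (dir in c("left", "right")) {
    cur <- ehh_oracle(hap, core, allele, dir, cutoff)
    if (is.null(cur)) return(NA_real_)
    if (length(cur$markers) > 1) {
      p <- positions[cur$markers]
      for (k in 2:length(p)) {
        total <- total + abs(p[k] - p[k - 1]) *
          (cur$ehh[k] + cur$ehh[k - 1]) / 2
      }
    }
  }
  total
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive enumeration over
# all tables with the observed margins (sum of point probabilities not
# exceeding the observed one, with the standard relative tolerance).
fisher_2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  point <- function(a) {
    stats::dhyper(a, c1, N - c1, r1)
  }
  p_obs <- point(tab[1, 1])
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  total <- 0
  for (a in lo:hi) {
    pa <- point(a)
    if (pa <= p_obs * (1 + 1e-7)) total <- total + pa
  }
  min(total, 1)
}

# Brute-force interval overlap (half-open) between genes and regions.
overlap_oracle <- function(genes, regions) {
  hit <- logical(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    for (r in seq_len(nrow(regions))) {
      if (genes$chrom[g] == regions$chrom[r] &&
          genes$start[g] < regions$end[r] &&
          genes$end[g] > regions$start[r]) {
        hit[g] <- TRUE
      }
    }
  }
  sort(unique(genes$gene_id[hit]))
}
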