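test_that("allele frequencies count non-missing calls only", {
  d <- rbind(c(1), c(1), c(1), c(1), c(1))
  gm <- toy_gm(cbind(d, c(0, 1, 2, 2, NA), c(NA, NA, NA, NA, NA)),
               n_a = 3)
  af <- allele_frequencies(gm)
  expect_equal(af$alt_freq[1], 0.5)
  expect_equal(af$maf[1], 0.5)
  # dosages (0,1,2,2,NA): 5 alt alleles over 8 called copies
  expect_equal(af$alt_freq[2], 5 / 8)
  expect_equal(af$maf[2], 3 / 8)
  expect_true(is.na(af$alt_freq[3]))
  expect_equal(af$n_called[3], 0L)
})

test_that("MAF spectrum bins sum to the defined-site count", {
  d <- cbind(c(1, 1, 1, 1, 1), c(0, 0, 0, 0, 1), rep(NA, 5))
  gm <- toy_gm(d, n_a = 3)
  sp <- maf_spectrum(gm, n_bins = 5)
  expect_equal(sum(sp$count), 2)
  expect_equal(sp$count[5], 1)  # maf 0.5 lands in the closed last bin
  expect_equal(sp$count[2], 1)  # maf 0.1 in [0.1, 0.2)
  # hand-binned toy: minor-allele counts 0..5 over 10 copies, two bins
  # with an exactly representable edge at 0.25
  ks <- c(0, 1, 2, 3, 5, 5)
  dos <- vapply(ks, function(k) c(rep(1, k), rep(0, 5 - k)), numeric(5))
  gm2 <- toy_gm(dos, n_a = 3)
  sp2 <- maf_spectrum(gm2, n_bins = 2)
  expect_equal(sp2$count, c(3, 3))
})

test_that("heterozygosity rate is het calls over called genotypes", {
  expect_equal(heterozygosity_rate(toy_gm(matrix(1, 4, 3))), 1)
  expect_equal(heterozygosity_rate(toy_gm(matrix(2, 4, 3))), 0)
  d <- matrix(c(1, 1, 1, 1, 0, 2, 0, 2, 0, 2), 2, 5)
  expect_equal(heterozygosity_rate(toy_gm(d)), 0.4)
})

test_that("ts/tv classifies REF/ALT pairs and needs polymorphism", {
  gm <- toy_gm(matrix(1, 4, 4),
               ref = c("A", "C", "A", "G"),
               alt = c("G", "T", "T", "C"))
  expect_equal(ts_tv_ratio(gm), 1)  # {A>G, C>T} ts; {A>T, G>C} tv
  gm_ts <- toy_gm(matrix(1, 4, 1), ref = "A", alt = "G")
  expect_true(is.na(ts_tv_ratio(gm_ts)))  # zero transversions
  gm_tv <- toy_gm(matrix(1, 4, 1), ref = "A", alt = "T")
  expect_equal(ts_tv_ratio(gm_tv), 0)
  # monomorphic sites are excluded
  gm_mono <- toy_gm(cbind(rep(0, 4), rep(1, 4)),
                    ref = c("A", "A"), alt = c("G", "T"))
  expect_equal(ts_tv_ratio(gm_mono), 0)
})

test_that("FST is 1 at a fixed difference and <= 0 without differentiation", {
  gm <- toy_gm(matrix(rep(c(0, 2), each = 5), 10, 4), n_a = 5)
  fst <- fst_per_site(gm)
  expect_equal(fst$value, rep(1, 4))
  same <- matrix(rep(c(0, 1, 2, 1, 0), 2), 10, 3)
  gm2 <- toy_gm(same, n_a = 5)
  expect_true(all(fst_per_site(gm2)$value <= 0))
})

test_that("FST handles degenerate and undercalled sites", {
  gm <- toy_gm(cbind(rep(0, 10), c(rep(NA, 4), 1, rep(1, 5))), n_a = 5)
  fst <- fst_per_site(gm)
  expect_equal(fst$value[1], 0)       # monomorphic in both -> defined 0
  expect_true(is.na(fst$value[2]))    # one called genotype in group A
})

test_that("Weir-Cockerham FST matches the variance-components oracle", {
  set.seed(42)
  for (rep in 1:30) {
    gm <- random_gm(5, S = 10, miss = ifelse(rep %% 3 == 0, 0.1, 0))
    fst <- fst_per_site(gm)
    for (s in seq_len(10)) {
      expected <- wc_theta_oracle(gm$geno[1:5, s], gm$geno[6:10, s])
      if (is.na(expected)) expect_true(is.na(fst$value[s]))
      else expect_equal(fst$value[s], expected, tolerance = 1e-12)
    }
  }
})

test_that("Hudson estimator is near zero without differentiation", {
  set.seed(7)
  gm <- random_gm(5, S = 2000)
  h <- fst_per_site(gm, estimator = "hudson")
  expect_lt(abs(mean(h$value, na.rm = TRUE)), 0.02)
  expect_true(all(h$value <= 1, na.rm = TRUE))
})

test_that("window_mean averages defined sites and honors min_snps", {
  tr <- tibble::tibble(chrom = "chr1", pos = c(10000, 20000),
                       value = c(0.2, 0.4))
  w <- window_mean(tr, 50000, min_snps = 1,
                   chrom_lengths = c(chr1 = 50000))
  expect_equal(w$value, 0.3)
  w2 <- window_mean(tr, 50000, min_snps = 10,
                    chrom_lengths = c(chr1 = 50000))
  expect_true(is.na(w2$value))
  expect_equal(w2$n_snps, 2L)
})

test_that("windows partition a 120 kb chromosome with a short tail", {
  tr <- tibble::tibble(chrom = "chr1", pos = c(1, 60000, 110000),
                       value = c(1, 2, 3))
  w <- window_mean(tr, 50000, min_snps = 1,
                   chrom_lengths = c(chr1 = 120000))
  expect_equal(w$start, c(0, 50000, 100000))
  expect_equal(w$end, c(50000, 100000, 120000))
  expect_equal(w$value, c(1, 2, 3))
})

test_that("every defined site lands in exactly one non-overlapping window", {
  set.seed(11)
  tr <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                       pos = sample.int(99999, 200),
                       value = rnorm(200))
  tr <- dplyr::distinct(tr, chrom, pos, .keep_all = TRUE) |>
    dplyr::arrange(chrom, pos)
  w <- window_mean(tr, 10000, min_snps = 0,
                   chrom_lengths = c(chr1 = 1e5, chr2 = 1e5))
  expect_equal(sum(w$n_snps), nrow(tr))
})

test_that("z_transform standardizes genome-wide and rejects degenerate", {
  tr <- tibble::tibble(chrom = "chr1", start = c(0, 1, 2) * 1e4,
                       end = c(1, 2, 3) * 1e4, n_snps = 10L,
                       value = c(1, 2, 3))
  z <- z_transform(tr)
  expect_equal(z$value, c(-1, 0, 1))
  expect_equal(attr(z, "genomewide_mean"), 2)
  expect_equal(attr(z, "genomewide_sd"), 1)
  expect_error(z_transform(dplyr::mutate(tr, value = 5)), "degenerate")
  # mean ~0, sd ~1 over defined windows; rank order preserved
  set.seed(3)
  tr2 <- tibble::tibble(chrom = "chr1", start = (0:99) * 1e4,
                        end = (1:100) * 1e4, n_snps = 10L,
                        value = c(rgamma(98, 2), NA, NA))
  z2 <- z_transform(tr2)
  v <- z2$value[!is.na(z2$value)]
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sd(v) - 1), 1e-9)
  expect_equal(order(v), order(tr2$value[!is.na(tr2$value)]))
})

test_that("Hp follows the pooled-heterozygosity closed form", {
  # one SNP with balanced counts (5 maj, 5 min) -> 0.5
  gm <- toy_gm(cbind(c(1, 1, 1, 1, 1, rep(0, 5))), n_a = 5)
  hp <- pooled_heterozygosity(gm, "A", window_size = 10000,
                              chrom_lengths = c(chr1 = 10000))
  expect_equal(hp$value, 0.5)
  # monomorphic window -> 0
  gm0 <- toy_gm(matrix(0, 10, 3), n_a = 5)
  hp0 <- pooled_heterozygosity(gm0, "A", 10000,
                               chrom_lengths = c(chr1 = 10000))
  expect_equal(hp0$value, 0)
  # (9,1) + (7,3) toy window -> 2*16*4/400 = 0.32
  dA <- rbind(c(1, 1), c(0, 1), c(0, 1), c(0, 0), c(0, 0))
  gm2 <- toy_gm(rbind(dA, matrix(0, 5, 2)), n_a = 5)
  hp2 <- pooled_heterozygosity(gm2, "A", 10000,
                               chrom_lengths = c(chr1 = 10000))
  expect_equal(hp2$value, 0.32)
})

test_that("Hp stays in [0, 0.5] and hits 0.5 only at balanced counts", {
  set.seed(5)
  for (i in 1:20) {
    gm <- random_gm(5, S = 30, miss = 0.05)
    hp <- pooled_heterozygosity(gm, "B", 1000,
                                chrom_lengths = c(chr1 = 3000))
    v <- hp$value[!is.na(hp$value)]
    expect_true(all(v >= 0 & v <= 0.5 + 1e-12))
  }
})

test_that("Tajima's D matches the independently transcribed constants", {
  set.seed(9)
  for (i in 1:20) {
    n_dip <- sample(3:6, 1)
    S <- sample(5:40, 1)
    j <- sample(0:(2 * n_dip), S, replace = TRUE)
    # build dosage columns realizing each count j over n_dip diploids
    dos <- vapply(j, function(k) {
      alleles <- sample(c(rep(1, k), rep(0, 2 * n_dip - k)))
      alleles[seq(1, 2 * n_dip, 2)] + alleles[seq(2, 2 * n_dip, 2)]
    }, numeric(n_dip))
    gm <- toy_gm(rbind(dos, dos), n_a = n_dip)  # group A = first half
    td <- tajimas_d(gm, "A", window_size = 1e5,
                    chrom_lengths = c(chr1 = 1e5))
    expect_equal(td$value, tajima_oracle(j, 2 * n_dip),
                 tolerance = 1e-10)
  }
})

test_that("Tajima's D is undefined without segregating sites and is more
           negative for singleton-heavy windows", {
  gm <- toy_gm(matrix(0, 10, 4), n_a = 5)
  td <- tajimas_d(gm, "A", 1e5, chrom_lengths = c(chr1 = 1e5))
  expect_true(is.na(td$value))
  n <- 10; S <- 12
  d_single <- tajima_oracle(rep(1, S), n)
  d_mid <- tajima_oracle(rep(5, S), n)
  expect_lt(d_single, d_mid)
})
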