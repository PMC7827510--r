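win_track <- function(values, chrom = "chr1", size = 50000,
                      stat = "z_fst") {
  n <- length(values)
  tr <- tibble::tibble(chrom = chrom, start = (0:(n - 1)) * size,
                       end = (1:n) * size, n_snps = 10L, value = values)
  attr(tr, "statistic") <- stat
  tr
}

test_that("call_regions merges adjacent significant windows", {
  tr <- win_track(c(6, 5.5, 1, 7))
  reg <- call_regions(tr, 5, "greater", method = "FST")
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(0, 150000))
  expect_equal(reg$end, c(100000, 200000))
  expect_equal(reg$peak_value, c(6, 7))
  expect_equal(reg$member_windows, c(2L, 1L))
  expect_equal(reg$direction, c("nondirectional", "nondirectional"))
})

test_that("call_regions returns an empty frame below threshold and breaks
           runs at undefined windows and sign flips", {
  expect_equal(nrow(call_regions(win_track(c(1, 2)), 5, "greater")), 0)
  # undefined window between two significant ones breaks the run
  tr <- win_track(c(6, NA, 6))
  reg <- call_regions(tr, 5, "greater")
  expect_equal(nrow(reg), 2)
  # opposite signs in adjacent windows -> two regions, directions A and B
  tr2 <- win_track(c(3, -3))
  reg2 <- call_regions(tr2, 2, "abs_greater", method = "XPEHH")
  expect_equal(reg2$direction, c("A", "B"))
  expect_equal(reg2$peak_value, c(3, -3))
})

test_that("region merging is idempotent", {
  set.seed(17)
  tr <- win_track(rnorm(60, sd = 3))
  reg <- call_regions(tr, 2.5, "abs_greater")
  # rebuild a window track from the merged regions and call again
  tr2 <- tibble::tibble(chrom = reg$chrom, start = reg$start,
                        end = reg$end, n_snps = reg$member_windows,
                        value = reg$peak_value)
  reg2 <- call_regions(tr2, 2.5, "abs_greater")
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
  expect_equal(reg2$direction, reg$direction)
})

test_that("genes_in_regions applies half-open overlap with deduplication", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    gene_name = gene_id, chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(100, 300, 140, 150, 1000), end = c(200, 400, 160, 300, 1100),
    strand = "+")
  regions <- tibble::tibble(chrom = c("chr1", "chr1"),
                            start = c(150, 1050), end = c(300, 1200),
                            method = "FST", direction = "nondirectional",
                            peak_value = 6, member_windows = 1L)
  hit <- genes_in_regions(regions, genes)
  # g1 overlaps [150,300); g2 abuts at 300 (half-open: excluded);
  # g3 ends at 160 (1 bp overlap); g4 wrong chromosome; g5 overlaps
  expect_equal(sort(hit$gene_id), c("g1", "g3", "g5"))
  expect_equal(sort(hit$gene_id), overlap_oracle(genes, regions))
})

test_that("genes_in_regions matches the brute-force oracle on random
           instances and warns on chromosome mismatch", {
  set.seed(23)
  for (i in 1:10) {
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", 1:15), gene_name = gene_id,
      chrom = sample(c("chr1", "chr2"), 15, TRUE),
      start = sample.int(5000, 15))
    genes$end <- genes$start + sample.int(500, 15)
    genes$strand <- "+"
    regions <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 4, TRUE),
      start = sample.int(5000, 4), method = "FST",
      direction = "nondirectional", peak_value = 6, member_windows = 1L)
    regions$end <- regions$start + sample.int(800, 4)
    hit <- genes_in_regions(regions, genes)
    expect_equal(sort(hit$gene_id), overlap_oracle(genes, regions))
  }
  bad <- tibble::tibble(chrom = "1", start = 0, end = 100, method = "FST",
                        direction = "nondirectional", peak_value = 6,
                        member_windows = 1L)
  expect_warning(genes_in_regions(bad, genes), "no shared chromosome")
})

test_that("combine_methods obeys inclusion-exclusion", {
  cm <- combine_methods(c("a", "b"), c("b", "c"))
  expect_equal(cm$n_union, 3)
  expect_equal(cm$intersection, "b")
  cm2 <- combine_methods(c("a"), c("b"))
  expect_equal(cm2$n_intersection, 0)
  set.seed(29)
  for (i in 1:10) {
    f <- sample(letters, sample(5:15, 1))
    x <- sample(letters, sample(5:15, 1))
    cm <- combine_methods(f, x)
    expect_equal(cm$n_union,
                 length(unique(f)) + length(unique(x)) - cm$n_intersection)
  }
})

test_that("rank_coding_variants filters to protein-altering sites and
           sorts by descending FST with positional tie-break", {
  eff <- c("nonsynonymous", "synonymous", "nonsynonymous", "stopgain",
           NA, "nonsynonymous")
  d <- matrix(rbinom(60, 2, 0.4), 10, 6)
  gm <- toy_gm(d, effect = eff, n_a = 5)
  fst <- tibble::tibble(chrom = "chr1", pos = gm$sites$pos,
                        value = c(0.11, 0.9, 0.45, 0.0, 0.8, 0.45))
  iv <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  rk <- rank_coding_variants(gm, fst, iv)
  # kept: sites 1,3,4,6 (protein-altering); order 0.45,0.45,0.11,0
  expect_equal(rk$fst, c(0.45, 0.45, 0.11, 0))
  expect_equal(rk$pos, c(300, 600, 100, 400))  # tie at 0.45: pos order
  expect_true(all(c("alt_freq_a", "alt_freq_b") %in% names(rk)))
  # empty when the interval holds no protein-altering site
  iv2 <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000)
  expect_equal(nrow(rank_coding_variants(gm, fst, iv2)), 0)
})

test_that("enrichment uses the hypergeometric tail with BH adjustment", {
  universe <- sprintf("g%02d", 1:40)
  gene_set <- universe[1:10]
  term_map <- list(t1 = universe[1:5],    # all in set
                   t2 = universe[31:35],  # none in set
                   t3 = universe[6:20])
  e <- enrich(gene_set, universe, term_map)
  t1 <- e[e$term == "t1", ]
  expect_equal(t1$n_overlap, 5)
  expect_equal(t1$p, phyper(4, 5, 35, 10, lower.tail = FALSE))
  expect_equal(e$p[e$term == "t2"], 1)  # overlap 0 -> P(X >= 0) = 1
  expect_error(enrich(gene_set, character(0), term_map), "empty")
  # single term: adjusted equals raw
  e1 <- enrich(gene_set, universe, term_map["t1"])
  expect_equal(e1$p_adj, e1$p)
})

test_that("BH adjustment reproduces the hand case and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    adj <- p.adjust(p, "BH")
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("genotype distribution test matches exhaustive enumeration", {
  expect_equal(genotype_distribution_test(rbind(c(5, 5), c(5, 5))), 1)
  tab <- rbind(c(8, 2), c(1, 9))
  expect_equal(genotype_distribution_test(tab), fisher_2x2_oracle(tab),
               tolerance = 1e-12)
  expect_lt(genotype_distribution_test(rbind(c(0, 10), c(10, 0))), 0.001)
  set.seed(37)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    expect_equal(genotype_distribution_test(tab), fisher_2x2_oracle(tab),
                 tolerance = 1e-10)
  }
  expect_error(genotype_distribution_test(rbind(c(0, 0), c(1, 2))),
               "margin")
  p23 <- genotype_distribution_test(rbind(c(4, 3, 1), c(0, 2, 6)))
  expect_true(p23 > 0 && p23 < 1)
})
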