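#' Site indices inside a set of genomic intervals
#'
#' @param gm a [geno_matrix()].
#' @param intervals tibble with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Integer site indices.
#' @export
sites_in_regions <- function(gm, intervals) {
  keep <- rep(FALSE, nrow(gm$sites))
  for (i in seq_len(nrow(intervals))) {
    keep <- keep | (gm$sites$chrom == intervals$chrom[i] &
                      gm$sites$pos - 1 >= intervals$start[i] &
                      gm$sites$pos - 1 < intervals$end[i])
  }
  which(keep)
}

#' Allele-sharing distance matrix between samples
#'
#' `d(i, j)` is the mean over co-called sites of `|dosage_i - dosage_j| / 2`
#' — 0 for identical genotypes, 1 for opposite homozygotes at every site.
#' Sites missing in either sample of a pair are excluded pairwise. This is
#' a similarity-based distance for within-species SNP data, not a
#' substitution-model distance.
#'
#' @param gm a [geno_matrix()].
#' @param site_subset optional integer site indices (e.g. from
#'   [sites_in_regions()]) restricting the distance to sweep-region SNPs.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_distance <- function(gm, site_subset = NULL) {
  g <- gm$geno
  if (!is.null(site_subset)) g <- g[, site_subset, drop = FALSE]
  n <- nrow(g)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok)) {
        stop("samples ", gm$samples[i], " and ", gm$samples[j],
             " share no called sites", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(abs(g[i, ok] - g[j, ok])) / 2
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining (via \pkg{ape}); exact on additive
#' distances. Negative branch-length estimates are clamped to zero, with
#' the number of clamped branches recorded in the `n_clamped` attribute.
#'
#' @param dm symmetric distance matrix with sample dimnames.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-12)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (nrow(dm) < 3) stop("need at least three samples", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dm))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Serialize a tree to Newick text
#'
#' @param tree a `phylo` tree.
#' @return Newick string with branch lengths (round-trips through
#'   [ape::read.tree()]).
#' @export
to_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Do the two groups form monophyletic clusters on a tree?
#'
#' Used to contrast the whole-genome tree (groups typically intermixed)
#' with the sweep-SNP tree (groups separated) on an unrooted tree: the
#' split is clean iff either group is a monophyletic clade under rooting
#' at the other side.
#'
#' @param tree a `phylo` tree whose tip labels are sample ids.
#' @param groups named group vector (sample -> "A"/"B").
#' @return `TRUE` if the A/B bipartition is an edge of the tree.
#' @export
groups_are_separated <- function(tree, groups) {
  a <- names(groups)[groups == "A"]
  a <- intersect(tree$tip.label, a)
  b <- setdiff(tree$tip.label, a)
  if (length(a) == 0 || length(b) == 0) return(FALSE)
  unrooted <- ape::unroot(tree)
  ape::is.monophyletic(unrooted, a) || ape::is.monophyletic(unrooted, b)
}
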