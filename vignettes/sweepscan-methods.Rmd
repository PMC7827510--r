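---
title: "Methods: two-population selective-sweep scans with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population selective-sweep scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
library(dplyr)
```

## The problem

When one subgroup of a population has been driven by recent selection —
artificial selection on a production trait is the archetype, e.g.
high-fecundity versus low-fecundity sheep within one breeding nucleus — a
beneficial haplotype rises toward fixation in that subgroup. This leaves
three linked footprints around the selected locus: extreme
allele-frequency differentiation between the subgroups (FST), depressed
local diversity in the selected subgroup (pooled heterozygosity, Tajima's
D), and unusually long haplotypes (extended haplotype homozygosity).
`sweepscan` implements this battery for a two-group design of small
sample size (the defaults assume five diploid individuals per group) and
couples it to a simulator with planted ground truth so every stage is
testable end to end.

The two groups are labelled **A** (control-like; the low-fecundity /
monotocous analog in the motivating design) and **B** (the contrast
group). Signed statistics use the convention *positive implicates A,
negative implicates B*.

## Statistics

### Per-SNP FST and Z(FST) windows

The default per-site estimator is the Weir–Cockerham (1984)
two-population variance-components estimator θ = a/(a + b + c), computed
from the per-group sample sizes, allele frequencies and observed
heterozygote frequencies. It is the canonical choice when group sizes
are small (its correction terms are exact in n), and it can be negative
at undifferentiated sites; negative values are deliberately **not**
clamped before window averaging, because clamping would bias window
means upward. A Hudson-type estimator with the Bhatia small-sample
correction is available via `fst_per_site(gm, estimator = "hudson")`.
Sites where either group has fewer than two called genotypes are flagged
`NA`; sites monomorphic in both groups are defined as 0 (all three
variance components vanish).

Window means use 50 kb non-overlapping windows by default (`step` is
configurable for sliding windows), require at least `min_snps = 10`
defined SNPs (guarding the Z tail against single-SNP windows), and are
Z-transformed with the genome-wide mean and sample standard deviation
pooled over all chromosomes supplied (autosomes and X alike). Outlier
windows are called at Z(FST) > 5 and merged into maximal runs of
adjacent/overlapping windows; an undefined window breaks a run. FST
regions are nondirectional (the statistic is unsigned).

### EHH, iHH and XP-EHH

For a core site and allele, EHH at marker x is the probability that two
random carrier haplotypes are identical over the whole segment from the
core to x: `EHH(x) = sum_h C(|class h|, 2) / C(n_carriers, 2)`. The
curve starts at 1 and is non-increasing outward; extension stops when
EHH < 0.05 (configurable) or the chromosome end is reached, and the
stopping marker is included as the final trapezoid endpoint. iHH is the
trapezoidal integral of the curve against physical distance in bp,
summed over both directions. Physical distance is the only measure — no
genetic map is consumed, as none is assumed available.

XP-EHH at a site is `ln iHH_A − ln iHH_B`, where each group's iHH pools
**all** haplotypes of that group with an allele-agnostic core (the core
site does not partition; this is the cross-population convention, unlike
the allele-specific curves of iHS, which remain available through
`ehh()`/`ihh()`). Raw scores are standardized genome-wide in a single
unbinned pass; windows then average the already-normalized scores, and
the fixed |XP-EHH| > 2 rule is applied to those window means without
re-standardizing (matching the printed form of the threshold). Region
runs carry the direction of their sign and break when the sign flips.
Sites where either group's iHH is zero or undefined are flagged `NA`.
The raw score is computed as a difference of logarithms rather than the
log of a quotient so that exchanging the groups negates every score
bit-exactly.

Two boundary caveats are inherent to the construction: curves that reach
a terminal marker integrate only to that marker (no edge correction),
and a chromosome's first/last sites therefore carry one-sided iHH.

### Pooled heterozygosity Hp

Per window (10 kb default), major and minor allele counts are summed
over SNPs within the analyzed group (counts over non-missing calls;
major/minor is resolved per site within that group, an exact 50/50 tie
deterministically assigning REF as major), and

Hp = 2 ΣnMAJ ΣnMIN / (ΣnMAJ + ΣnMIN)².

Hp lies in [0, 0.5], equals 0.5 iff the summed counts balance, and drops
toward 0 where a sweep has removed variation. Windows with no called
alleles are undefined.

### Tajima's D

The standard 1989 normalization D = (π − S/a₁)/√(e₁S + e₂S(S−1)), with π
accumulated from per-site called-copy counts (2j(n−j)/(n(n−1)) per
site). With missing data the constants use the window median of called
allele copies — a VCFtools-like approximation that avoids recomputing
the constants per site; with complete data it is exact. The window size
defaults to 50 kb (configurable; the statistic's bin size is a free
choice in this design). Windows without segregating sites are undefined.

### LD decay

r² (and D′) from phased haplotype counts, averaged within left-closed
right-open physical-distance bins over a seeded random sample of sites
passing a MAF filter (default 0.1, mirroring common practice for LD
summaries). Phased input is complete by contract, so the missingness
cutoff parameter exists only for interface parity.

### Trees

Distances are allele-sharing on dosages, d(i,j) = mean |dᵢ − dⱼ|/2 over
co-called sites — a similarity measure appropriate for within-population
SNP data, not a substitution-model distance. Trees are Saitou–Nei
neighbor joining (exact on additive matrices); negative branch estimates
are clamped to zero with a count kept on the tree. The characteristic
sweep signature is the contrast between the whole-genome tree (groups
intermixed) and a tree built from the most FST-differentiated SNPs
(groups split into two clades); `groups_are_separated()` tests whether
the A/B bipartition is an edge of the unrooted tree.

### Genes, enrichment, genotype tables

A gene is assigned to a region iff the half-open intervals overlap by at
least 1 bp; genes hitting several regions are deduplicated by id before
counting. Enrichment is database-free: term→gene maps are user-supplied,
p-values come from the one-sided hypergeometric tail (overlap 0 giving
p = 1 under P(X ≥ 0)), and adjustment is Benjamini–Hochberg. Genotype
distributions at a candidate mutation are compared between groups with
Fisher's exact test by default (appropriate at resequencing-panel sample
sizes; chi-square selectable), two-sided.

## The simulator

`simulate_sweep_data()` draws site positions as a Poisson process (mean
spacing 200 bp), gives each site a derived-allele frequency from a
1/k-shaped spectrum over the 4n chromosome copies (the neutral SFS
expectation; the exponent is configurable), and lets every haplotype
draw its background alleles independently from that shared frequency —
so neutral FST is ~0 in expectation and background sites are unlinked.
Inside a sweep interval a fixed core haplotype is planted: each
haplotype copies it with probability `carrier_freq` of its group (0.9
selected / 0.1 other by default — a near-fixed hard sweep that is still
polymorphic overall), with copied alleles flipped at a 1% per-site rate
to mimic mutation/recombination leakage on the core. Genotypes are sums
of haplotype pairs; REF/ALT bases are drawn with a 70% transition bias
(ts/tv ≈ 2.3, the mammalian ballpark); optional uniform missingness
exercises missing-data paths (genotypes only — haplotypes stay
complete).

What the simulator deliberately does **not** emulate: background LD
(all LD comes from planted cores, so LD-decay monotonicity must be
exercised with correlated fixtures), recombination maps, demography and
soft sweeps. Passing tests therefore demonstrate the statistics'
behavior under a clean hard-sweep signal with unlinked background, not
performance on demographically complex real data.

The default study design — two groups of five diploids, 2 × 2 Mb
chromosomes, one 50 kb sweep in group B — mirrors the motivating
two-group resequencing design at desk scale. Replicate experiments in
the tests and the acceptance script use a single 2 Mb chromosome (50
replicates for sweep recovery and Hp depression) and a 4 Mb chromosome
(20 replicates for the tree contrast): the tree experiment needs a
larger neutral background because whole-genome distances on a short
chromosome would be dominated by the sweep itself, whereas in a real
genome the sweep is a vanishing fraction of all SNPs. The sweep-SNP
tree follows the FST-ranked-SNP construction (top 200 sites by
single-site FST), which is how such trees are built in practice.

## Numerical choices and degenerate inputs

- Coordinates: 0-based half-open internally and in BED output; 1-based
  inclusive in VCF. Window `[start, end)` contains a VCF position p iff
  start ≤ p − 1 < end.
- Undefined values are explicit `NA`s, never silent zeros; they are
  excluded from normalizations and break region runs.
- `z_transform()` refuses constant tracks (zero sd) and tracks with
  fewer than two defined windows; `xpehh()` warns and returns `NA`
  normalized scores when the raw distribution is degenerate (e.g.
  identical groups), keeping the raw scores.
- Multi-allelic VCF records are skipped (not split) and counted —
  every statistic here is defined on biallelic SNPs. Half-calls
  (`./1`) are treated as fully missing (conservative; avoids dosage
  ambiguity). Effect classes are read from an INFO key (default
  `ANN_CLASS`) and never computed.
- Site filters compute thresholds on the retained sample set, so
  dropping samples then filtering equals filtering then dropping.
- Ties: Hp major-allele ties assign REF as major; equal-FST variants
  rank by (chrom, pos); NJ tie behavior is delegated to ape's
  implementation.
- The EHH kernel is compiled (Rcpp) because per-site iHH scans over
  ~10⁴-site chromosomes × replicates are the pipeline's hot loop.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `fst_window`, `xpehh_window` | 50,000 | bp | window size for FST/XP-EHH means |
| `hp_window` | 10,000 | bp | Hp window size |
| `tajima_window` | 50,000 | bp | Tajima's D bin size |
| `zfst_threshold` | 5 | – | Z(FST) calling cut |
| `xpehh_threshold` | 2 | – | cut on windowed |XP-EHH| |
| `min_snps` | 10 | SNPs | minimum defined SNPs per window |
| `ehh_cutoff` | 0.05 | – | EHH truncation threshold |
| `estimator` | `"wc"` | – | FST estimator (`"wc"`/`"hudson"`) |
| `snp_spacing` | 200 | bp | simulator mean SNP spacing |
| `carrier_freq_*` | 0.9 / 0.1 | – | simulator sweep penetrance |

Steps equal window sizes by default (non-overlapping partition); set a
smaller step for sliding windows.

## Open design points, resolved

- *Sliding vs non-overlapping windows*: non-overlapping is the default
  (it is the form under which the fixed thresholds are interpretable and
  the reported analyses are framed); the step remains configurable.
- *Which windows enter the Z(FST) normalization*: all supplied
  chromosomes are pooled (autosomes and X together when both are given).
- *Windowed XP-EHH thresholding*: the |2| cut applies to window means of
  genome-wide-normalized per-site scores; window means are not
  re-standardized.
- *Site-level QC before the scan*: none by default; `filter_sites()`
  exposes generic MAF/missingness/chromosome filters for callers that
  want them.
- *The genotype-table test*: Fisher's exact by default — at two groups
  of a few dozen animals the exact test is the defensible choice; the
  chi-square alternative is selectable for larger panels.

## Limitations

Two groups only (no multi-population FST); hard sweeps are the
simulator's only signal model; no phasing or imputation (phased input is
consumed as-is and must be complete); no genetic maps; NJ only (no
likelihood trees); enrichment needs user-supplied term maps and does no
ontology propagation. The tree-contrast and recovery rates quoted by the
test suite are properties of the simulator's clean hard-sweep model and
transfer to real data only qualitatively.

## A minimal run

```{r example, eval = FALSE}
cfg  <- sweep_sim_config(seed = 42)
sim  <- simulate_sweep_data(cfg)
lens <- setNames(cfg$chrom_specs$length, cfg$chrom_specs$name)
scan <- scan_sweeps(sim$gm, sim$haps, chrom_lengths = lens)
tidy(scan)      # called regions, with method and direction
glance(scan)    # one-row summary
plot_manhattan(scan$zfst, threshold = 5)
```
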