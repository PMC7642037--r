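---
title: "Methods: co-expression networks, modules, and promoter motif enrichment"
author: "coexfun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, modules, and promoter motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexfun)
```

# Overview

`coexfun` turns a gene × sample FPKM matrix into (i) signed co-expression
networks with a data-driven correlation cutoff, (ii) WGCNA-style functional
modules, (iii) gene-set over-representation statistics for arbitrary gene
lists, and (iv) an empirical promoter cis-element enrichment score. It is
species-agnostic: everything it needs (expression TSV, GFF3 + genome FASTA,
GMT gene sets, an IUPAC motif table, ortholog pairs and source-species PPI
edges) is plain text, and a bundled simulator generates all of it with known
ground truth.

This vignette explains the statistical model behind each stage, the tunable
parameters with their defaults and the reasoning behind them, what the
simulator does and does not emulate, and the numerical conventions that make
runs reproducible.

# Co-expression networks

## Correlation and filtering

Co-expression between genes $x$ and $y$ is the Pearson correlation of their
expression across the $n$ samples,

$$
r_{xy} = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
  {\sqrt{\sum_i (x_i-\bar x)^2\,\sum_i (y_i-\bar y)^2}},
$$

computed after a minimal expression filter: a gene must reach
`min_fpkm` (default 1 FPKM) in at least `min_expressed_samples` (default 2)
samples, and must not be constant. The filter defaults are deliberately
mild — correlation is scale-free in the gene's mean level, so filtering is
only needed to remove genes whose correlations are numerically undefined or
dominated by detection noise. Both knobs are exposed on
`correlation_matrix()` and on the CLI.

## Choosing the cutoff

Biological networks are expected to be approximately scale-free and sparse.
The toolkit therefore scans a grid of candidate cutoffs (the conventional
grid is $0.60, 0.65, \ldots, 0.95$) and records, for the graph thresholded
at each cutoff:

* edge count and the number of non-isolated nodes;
* network density $2E/(N(N-1))$, reported with two denominators —
  `density` over the full filtered gene set, which is monotone
  non-increasing in the cutoff, and `density_connected` over non-isolated
  nodes, which matches the shrinking node counts but can tick upward at
  extreme cutoffs when nodes disappear faster than edges;
* the scale-free fit index $R^2$: positive degrees are binned into 10
  equal-width bins (configurable; no binning convention is canonical, and
  10 bins is the common choice), and $R^2$ is the squared correlation
  between $\log_{10}$(bin frequency) and $\log_{10}$(mean bin degree).

`select_cutoff()` picks, among scanned cutoffs whose (full-universe)
density does not exceed `max_density`, the one with maximal $R^2$; ties go
to the smaller cutoff because the denser network retains more information.
Final networks use strict inequalities — `pcc > pos_cutoff` for the
positive network, `pcc < neg_cutoff` for the negative one — so a pair
sitting exactly at the cutoff is excluded.

The positive and negative networks are kept separate rather than combined
into an unsigned graph: anti-correlated regulation is a different biological
signal from co-regulation, and downstream neighborhood queries are usually
asked per sign.

# Functional modules

Module detection follows the weighted-network recipe:

1. **Soft threshold.** The unsigned adjacency is $a_{ij} = |r_{ij}|^\beta$
   with default $\beta = 7$; `soft_threshold_scan()` reports the
   scale-free fit of the connectivity distribution and the mean
   connectivity per candidate power so users can verify the choice on
   their own data. Unsigned adjacency is used because negative edges are
   handled separately by the signed networks above.
2. **Topological overlap.** Pairwise similarity is
   $\mathrm{TOM}_{ij} = (L_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
   with $L_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$ and
   $k_i = \sum_{u\ne i} a_{iu}$ — genes are similar when they are directly
   connected *and* share weighted neighborhoods, which is much more robust
   to single noisy correlations than adjacency alone.
3. **Clustering.** Average-linkage hierarchical clustering on
   $1-\mathrm{TOM}$, cut at a static height expressed as a fraction of the
   maximal merge height (`cut_height`, default 0.90), with clusters below
   `min_module_size` (default 30) relabelled `grey` (unassigned). This is
   a deliberately simplified variant of dynamic tree cutting: a single
   global height plus a minimum size. The full hybrid algorithm adapts the
   cut per branch; the static variant is transparent, deterministic, and
   sufficient for block-structured expression data.
4. **Eigengenes and merging.** Each module is summarized by its eigengene —
   the first principal component of the per-gene standardized member ×
   sample matrix, unit-normalized, with its sign fixed to correlate
   non-negatively with the module's mean standardized profile (principal
   components are sign-ambiguous; fixing the sign makes results
   reproducible). Modules whose eigengene dissimilarity $1 - r(E_i,E_j)$
   falls below `merge_cut_height` (default 0.25, the field's customary
   value) are merged iteratively, closest pair first, recomputing the
   merged eigengene after every step.

## Why the static cut sits at 0.90

With unsigned adjacency, unclustered background genes form a plateau of
dissimilarity just below 1: their topological overlap with any module is
nearly zero. But at realistic sample counts (tens of samples), a background
gene's sample correlation with a module's latent profile can reach
$|r| \approx 0.35$–$0.45$ purely by chance, which after $\beta = 7$
soft-thresholding still yields TOM values of a few percent — dissimilarity
0.95–0.99. Cutting at 0.99 of the maximal height therefore absorbs a
non-trivial number of background genes into every module. Module-internal
merges, by contrast, happen far below 0.85 whenever the within-module
correlation is moderate or better. The default cut of 0.90 sits in the gap
between those two regimes. The test suite exercises both effects: on
planted-module simulations the 0.90 cut recovers the planted partition
with a high adjusted Rand index, and raising the cut toward 0.99 is shown
to pull additional background genes into the modules. The parameter
remains configurable for data with different noise structure.

# Gene-set enrichment

Enrichment of a query gene list against a GMT collection is
over-representation analysis. With a universe of $N$ genes, a set of $K$,
a query of $n$ and an overlap of $k$, the default p-value is the
hypergeometric upper tail

$$
P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
  \frac{\binom{n}{i}\binom{N-n}{K-i}}{\binom{N}{K}},
$$

computed in log space. The point mass $P(X = k)$ is exposed separately
(`hypergeom_pmf()`); enrichment needs the tail, since "at least this much
overlap" is the question being asked. One-sided Fisher's exact test (which
coincides with the hypergeometric tail on the same margins, and is kept as
an independent code path so the two can cross-check each other) and the
Pearson $\chi^2$ test (no continuity correction by default) are available
alternatives. Six multiple-testing corrections are supported — Bonferroni,
Holm, Hochberg, Hommel, Benjamini–Hochberg, and Benjamini–Yekutieli —
applied across the tested sets.

By default only sets that overlap the query ($k \ge 1$) are tested and
counted in the correction; `include_empty = TRUE` changes both. The
universe defaults to the union of annotated genes in the collection and
can be overridden (e.g. with the full gene complement of the genome) —
with a genome-wide universe, sparse annotations make every set look more
enriched, so the choice should be stated with any result.

Because the hypergeometric distribution is discrete, the attained type-I
level at a nominal 0.05 is below 0.05 and depends on $N$, $K$ and $n$. The
calibration checks in the test suite use queries of 200 genes against a
2,000-gene universe with sets of 60–200 genes, where the attained level is
about 0.035–0.045; materially smaller queries would make the test
unfairly conservative purely through discreteness.

# Promoter motif enrichment

Promoters are the `length` bases (1, 2 or 3 kb) immediately upstream of
the annotated gene start — on the `-` strand, the reverse complement of
the bases immediately downstream of the annotated end — truncated at
contig boundaries, never clipped against neighboring genes. Truncated
promoters are kept (with their actual length recorded) so the query and
the null are drawn from the same gene universe; dropping them would bias
the null. Soft-masked bases are upper-cased before scanning.

A motif given as an IUPAC consensus is scanned with overlaps allowed, on
the forward strand and against the reverse complement of the promoter;
palindromic matches count once per strand. An `N` in the genome matches
only the motif letter `N`, so assembly gaps cannot fake matches.

For a query of $n$ genes, the observed statistic is the mean match count
$\bar X$ per query promoter. The null is empirical: $B = 1000$ random gene
lists of size $n$ are drawn (uniformly, without replacement within a
list) from the promoter universe, and the per-gene match counts of all
$B \cdot n$ sampled promoters are pooled into a null mean $\mu$ and
standard deviation $\sigma$. Then

$$
Z = \frac{\bar X - \mu}{\sigma/\sqrt n},
\qquad
P = 1 - \Phi(Z),
$$

and a motif is called significant at $P < 0.05$. Pooling per gene (rather
than across the $B$ list means) is the reading consistent with dividing
$\sigma$ by $\sqrt n$: if $\sigma$ were already the standard deviation of
list means, the $\sqrt n$ would shrink it twice. Both poolings are
implemented (`pooling = "per_gene"` or `"per_list_mean"`); per-gene is the
default. The null is scanned at the same promoter length as the query —
scanning the null at a fixed 3 kb while the query uses 1 kb would compare
incommensurable counts.

Two caveats are inherent to the method and worth knowing: the normal
approximation ignores the finite-population correction (sampling $n$ of
$U$ promoters without replacement shrinks the true standard error by
$\sqrt{1-\tfrac{n-1}{U-1}}$), making the test slightly conservative; and
motif match counts are discrete and right-skewed, so for very short
queries the upper tail is approximate. At the scales used in the
calibration tests ($n = 30$, $U = 500$, 1-kb promoters) the empirical
type-I rate at $P<0.05$ stays within 0.03–0.07.

A motif absent from (or constant across) the whole universe has
$\sigma = 0$; its Z is undefined and the result row is flagged
`degenerate` with $P$ set to 1 (or 0 if the observed mean still exceeds
the null mean) rather than crashing or silently reporting a number.

# Ortholog-based network transfer

`project_ppi()` implements interolog projection: ortholog pairs are
filtered at a bootstrap support strictly above `bootstrap_min`
(default 60%), and every source-species interaction $(s_1, s_2)$ emits all
target pairs $(t_1, t_2)$ with $s_1 \to t_1$, $s_2 \to t_2$, dropping
self-loops and collapsing duplicates. Projections from several source
species can be concatenated before deduplication; a `provenance` column,
when present, is merged (`"maize,rice"`) so the origin of each transferred
edge survives the union. `neighborhood_overlap()` counts ortholog pairs
between two genes' neighborhoods across species — the building block for
asking whether a gene's co-expression context is conserved.

# The simulator and what passing tests mean

`sim_spec()` fixes the synthetic study: 2,000 genes × 40 samples with five
planted modules of 200/160/120/90/60 genes by default. Each module's genes
share a Gaussian latent profile (sd 2) plus independent noise (sd 1), so
the expected within-module correlation is $s^2/(s^2+\varepsilon^2) = 0.8$;
the remaining genes are independent noise. Values are shifted by the
global minimum to a non-negative FPKM-like scale — correlations are
shift-invariant, so the planted truth is unchanged. The promoter universe
is 500 genes with 1-kb uniform-random promoters, a 20-motif library of
length-6 consensus motifs, and 3 copies of one motif planted into the
promoters of a 30-gene enriched set; genes are laid out one per contig on
alternating strands so the FASTA+GFF3 path is exercised end to end. A
separate generator plants a preferential-attachment (scale-free) graph
inside a correlation-like matrix for cutoff-selection tests.

The simulator emulates the *correlation structure* of a curated expression
compendium, not RNA-seq noise: real FPKM values are heteroskedastic,
zero-inflated and library-size dependent, real modules overlap and have
hub structure, and real promoters have composition bias and repeats.
Passing the bundled checks therefore demonstrates that the algorithms are
implemented correctly and calibrated under their own assumptions — not
that any particular biological dataset will yield well-separated modules.

# Numerical conventions

* All stochastic functions take an explicit seed and restore the caller's
  RNG state; identical seed + configuration gives byte-identical TSV/JSON
  outputs (manifests record the configuration, deliberately without
  timestamps).
* TSV numbers are written with 10 significant digits via a fixed format,
  so round-trips are stable to at least 6 significant digits.
* Hypergeometric probabilities use log-space binomial coefficients;
  impossible overlap configurations have probability 0 by convention.
* Module labels are assigned in decreasing size order (`M1` largest), with
  ties broken by the lexicographically smallest member gene, and the
  dendrogram cut, eigengene sign and merge order are all deterministic.
* Edge lists are canonicalized (`gene_a < gene_b`, sorted) on every write.

# Problem sizes used in the bundled checks

Oracle comparisons (correlation loop, exact-test enumerations, TOM triple
loop, correction references) run at 50–60 genes or $N \le 30$ tables where
brute force is exact and fast. Calibration checks use 400 replicate
queries (gene-set and motif null), $B = 1000$ null draws, 50 seeds for
motif power, and the default 2,000-gene expression study for module
recovery — sizes chosen so the full suite completes in a few minutes on a
single core while keeping Monte-Carlo error well inside the asserted
bands.

# Known limitations

* The static-height cut is a simplification of hybrid dynamic tree
  cutting; very unequal module densities may need a per-dataset
  `cut_height`.
* Unsigned adjacency folds anti-correlated genes into the same module if
  their |r| is high; use the signed networks when the distinction matters.
* The motif scanner is consensus-based by design; position-weight-matrix
  scoring is out of scope.
* `chisq_2x2()` is asymptotic and refuses tables with zero expected
  counts — use the exact test there.
* Interolog projection transfers edges, not confidence: bootstrap support
  filters orthology, but no interaction-level score is propagated.
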