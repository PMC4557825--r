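---
title: "Gene set compactness on cell-type-specific interactomes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set compactness on cell-type-specific interactomes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compactome)
```

# The model

`compactome` implements a network-propagation approach to a mapping
problem: given a set `S` of genes associated with a disease, identify the
cell types in which the disease is manifested. The premise is that
disease-associated genes participate in shared pathways, that pathways are
visible as clusters in protein-interaction networks, and that a pathway
disrupted by a disease is active — its genes expressed — in the cell types
the disease affects. So `S` should cluster most tightly in interaction
networks weighted by the expression of the disease-manifesting cell types.

## From counts to percentile profiles

Expression enters the model only through within-cell-type ranks. The chain
is:

1. **RLE normalization** (`rle_normalize()`): per-sample size factors are
   the median, over genes positive in every sample, of the ratio of the
   gene's count to its across-sample geometric mean; counts are divided by
   the factor and rescaled to one million per sample ("tags per million").
   The median is taken on the ratio scale, which makes the factors agree
   exactly with edgeR's RLE implementation (checked in a test).
2. **Sample QC** (`qc_filter_samples()`): replicate samples of one
   cell-type population (a *sub-facet*) are clustered by complete-linkage
   hierarchical clustering on pairwise Jensen–Shannon distances (JSD,
   base-2 logs so distances live on [0, 1]); the tree is cut at 0.35 and
   only the largest cluster survives. Singleton sub-facets, and sub-facets
   where no cluster has two samples, are dropped entirely. The cut height
   is a similarity tolerance on the JSD scale: 0.35 keeps honest replicates
   (JSD near 0) and discards swapped or failed samples.
3. **Combining** (`combine_samples()`): within each broader *facet*, the
   mean pairwise JSD decides whether the facet is one cell type (mean ≤
   0.25: average all samples into a single profile) or several (mean >
   0.25: one averaged profile per sub-facet). The threshold separates
   facets of interchangeable sub-populations from facets that mix
   genuinely distinct cell states.
4. **Relative expression** (`relative_expression()`): `e'_{i,l} =
   k e_{i,l} / Σ_j e_{i,j}`, so each expressed gene averages exactly 1
   across the `k` cell types; all-zero genes are set to 0 everywhere rather
   than NaN.
5. **Percentile scores** (`percentile_scores()`): per cell type, genes are
   ranked ascending in `e'` and rescaled to `(rank − 1)/(n − 1)`, ties
   taking the average rank. The most overexpressed gene scores exactly 1,
   the most underexpressed exactly 0, and each column is a uniform grid on
   [0, 1]. This rank transform is what makes interactome weights
   comparable across cell types: a handful of extremely expressed genes
   (hemoglobin in reticulocytes is the canonical case) would otherwise
   produce a few enormous edge weights that trap the random walker.
   `expression_diagnostics()` reports, per cell type, how many genes sit
   above the global top-0.1% relative expression value; a column whose
   count is an outlier has a profile the rank transform cannot fully
   repair, and the user can drop it before building networks. We
   deliberately do not automate that exclusion — it is a judgment call
   about data provenance, not a statistical rule.

For CAGE-style data, `aggregate_peaks_to_genes()` first collapses peak
counts to gene counts: a peak is assigned to a gene when its midpoint lies
within 500 bp of an annotated transcript 5′ end (BED-convention, 0-based
coordinates), nearest gene winning and exact ties going to both genes by
default (`multi = "first"` for the conservative alternative).

## Interactomes and distances

`build_cell_interactome()` weights each PPI edge by the product of its
endpoints' percentile scores, `w_{i,j,l} = x_{i,l} x_{j,l}`. No expression
cutoff is applied: a weight-0 edge is kept, so every cell type shares one
topology and the permutation test below compares like with like. Genes
without an expression score are removed (with a reported count) rather than
given weight 0 — they would otherwise form dead zero-weight stars that the
walk can never leave.

Distances are ranked random-walk-with-restart (RWR) visits
(`rwr_probabilities()`, `ranked_distances()`): iterate
`p^{t+1} = (1 − r) A p^t + r p^0` with `A` the column-normalized weighted
adjacency and `p^0` an identity column per source, until the Manhattan
distance between successive matrices falls below `|S| × 10⁻⁵`. With
`r = 0.7` the iteration contracts by 0.3 per step, so convergence takes
roughly ten iterations; only the columns for the source set `S` are
computed. Per source, vertices are ranked by steady-state probability
(rank 1 = most visited, ties averaged) and the ranks are the distances.
Ranks, not raw probabilities, make distances comparable across
differently-weighted networks.

Numerical details chosen here, where the method description is silent:

- **Dangling columns.** A vertex whose incident weights are all zero gives
  a zero column of `A`; mass reaching it would leak. We route that mass
  back to the walk's start vertex (the column behaves like a restart),
  which keeps every probability column summing to 1 to 10⁻⁸ — asserted at
  test time, and the natural continuous limit of "the walker has nowhere
  to go but home".
- **Rank ties** take the average of their positions: deterministic and
  symmetric under vertex relabeling.
- **Restart probability 1** is the degenerate limit: the walker never
  leaves its source, every column is `p^0` (used as a unit test).
- Dense iteration is used throughout; at the package's intended scales
  (up to a few thousand vertices) the dense matrix product is faster than
  sparse dispatch.

## The compactness and overexpression tests

The compactness of `S` on graph `G` is `C(S, G) = Σ_{i,j∈S} d(i,j)/|S|²`,
the mean ranked distance over *ordered* pairs — the `|S|²` denominator
implies self-pairs are included, and since `d(i,i)` is near 1 for every
source, including them shifts all compactness scores by the same small
amount and cancels in the permutation comparison. An `include_self =
FALSE` flag exists for sensitivity analysis.

Significance (`gsc_test()`) comes from rebuilding the interactome from
permuted expression: a permuted profile draws one cell-type column
uniformly at random and shuffles its gene assignment
(`permute_profiles()`), preserving the exact uniform score multiset the
weights rely on. The sentence describing the scheme admits a second
reading — independent per-gene resampling of both cell type and score —
which is available as `permute_method = "per_gene"`; the column-draw
default preserves the marginal exactly and is the one used everywhere.
The empirical P value is the proportion of `u` permuted interactomes with
strictly smaller compactness, floored at `1/u` (never 0); we use
`u = 10000` for production runs and `u = 200` inside the test suite.
Because a permuted interactome is built from a single permuted column, it
is the same network whichever cell type is being tested, so the permuted
compactness values are drawn once per disease and shared across cell types
(`reuse_permutations = FALSE` forces independent streams; it multiplies
cost by the number of cell types and changes nothing in expectation).

`gso_test()` applies the same machinery to the mean percentile score of
`S` (greater is more extreme) — no network, pure overexpression.
`rank_cell_types()` orders cell types by P value with ties broken by the
standardized effect size `(C_obs − mean(C_perm))/sd(C_perm)`; at small `u`
several cell types can hit the `1/u` floor and the effect size is the
natural refinement.

Both tests return tibbles; `adjust_fdr()` adds Benjamini–Hochberg q
values, by default across the whole disease × cell-type matrix (the
per-disease alternative is a flag — the global choice matches how the
association list is thresholded at FDR 10% downstream, and the method
description does not distinguish the two).

## Validation arm and the diseasome

`cooccurrence_fisher()` and `overlap_significance()` use a one-tailed
Fisher's exact test (enrichment direction), with the hypergeometric tail
accumulated by log-sum-exp over log masses: overlaps of realistic
association catalogues produce P values around 10⁻¹⁸⁰ that a naive
summation would handle but a naive product of factorials would not, and
the log-space path is exact wherever direct summation is feasible (checked
against both an exhaustive tail sum and `fisher.test` on small corpora).
The module consumes precomputed count tables; querying a live literature
database is out of scope because historical article counts are not
reproducible. `make_disease_bins()` groups diseases by gene-set size
(descending, greedy fill to 20, ties inseparable) and
`parameter_grid_eval()` sweeps interaction-confidence cutoffs and restart
probabilities, reporting precision/recall/F1 at FDR 10% against a
reference set.

`build_diseasome()` connects each disease to the `k = 4` diseases whose
−log10 q profiles over cell types correlate most strongly (Pearson), after
removing diseases with no association at FDR 10%. Correlation ties at rank
k break lexicographically for determinism; q values are bounded below by
the permutation floor `1/u`, so the logs are finite by construction.
Diseases with constant q profiles are excluded with a warning (their
correlation is undefined).

# The synthetic-data generator

`generate_synthetic_study()` emulates exactly the structure the method
assumes: an Erdős–Rényi background PPI network (300 genes, 1200 edges by
default — edge density ~2.7%, comparable to a confidence-filtered PPI
network), and per disease a 10-gene module wired at extra density 0.6 and
placed, in one target cell type, entirely at or above the 0.9 percentile.
Score columns are exact uniform grids, so generated profiles satisfy the
percentile invariants by construction. Targets are drawn without
replacement while diseases fit into distinct cell types, because modules
sharing a target column compete for the limited top-decile score slots;
when sharing is unavoidable the planting is done jointly per column and
errors out if slots run out, rather than silently weakening a module.

`generate_null_study()` (150 genes, 4 cell types, 600 edges, 8-gene sets
by default — a deliberately small replicate so hundreds of them fit in a
test run) has no planted structure at all: it is the fixture for
permutation-null calibration. Under the null the observed profile is
exchangeable with the permuted ones, so the empirical P value is uniform
on the `1/u` grid up to discreteness — the test suite verifies that the
fraction of P ≤ 0.05 over 200 replicate studies sits inside the 99%
binomial interval around 0.05, for both tests.

What the generator does *not* emulate: degree-correlated expression,
scale-free topology, hub-dominated PPI degree distributions, replicate
sample structure (in score mode), or any ontology structure among
diseases. Passing the planted-recovery and calibration suites therefore
demonstrates correctness of the statistical machinery under the model's
own assumptions, not performance on real atlas data. A count-level mode
(`expression_mode = "counts"`, negative-binomial counts with a boosted
module) exercises the full normalization chain end-to-end at the cost of
exact score placement.

# Problem sizes and determinism

Simulation-based checks run at deliberately modest sizes: oracle
equivalence on 50 random graphs of up to 50 vertices (iterative RWR vs
the direct solve `r (I − (1−r)A)⁻¹ p⁰`, compactness vs a brute-force
double loop), null calibration on 200 replicate null studies at
`u = 200`, planted recovery across 50 seeded studies at the generator
defaults. These sizes give stable verdicts (binomial half-widths of a few
percent) while keeping the whole suite in the low minutes. Every stochastic
step takes an explicit seed; a run with the same seed is bit-identical,
including the command-line interface's output files.

# Known limitations

- Compactness needs at least two genes of `S` in the graph; diseases with
  a single mapped gene are untestable by design (`filter_gene_sets()`
  defaults to six, the size at which the ranked-distance signal becomes
  reliable).
- The permutation null preserves the score *multiset* but not any
  gene-gene expression correlation; correlated expression modules in real
  data make the null conservative for sets overlapping them.
- Edge weights are products of marginal scores; co-expression information
  beyond marginal rank is not used.
- The literature arm treats the disease × cell-type product as the
  comparison universe and ignores ancestor/offspring term relationships;
  overlap significance is therefore a validation statistic, not a
  calibrated error rate.
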