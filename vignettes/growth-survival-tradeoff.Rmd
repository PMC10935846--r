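---
title: "Detecting growth-survival fitness trade-offs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting growth-survival fitness trade-offs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(growthtradeoff)
library(ggplot2)
```

# The scientific problem

Microbial strains cannot maximize growth and stress survival at once: strains
that allocate resources to rapid proliferation under favourable conditions tend
to fare worse under stress, and vice versa. Across a panel of yeast strains this
trade-off shows up as a *dichotomy* in the growth phenome: environmental
conditions split into two blocks — growth-favouring and stress-like — such that
growth values within a block correlate positively across strains while any pair
of conditions from opposite blocks anti-correlates. The same axis reappears at
the molecular level as a dominant two-arm gene-expression program: one arm
(PS, positive-scored genes; ribosome and ribonucleoprotein biogenesis) tracks
growth, the opposite arm (NS, negative-scored genes; catabolic and stress
response) tracks survival. This package implements the complete analysis chain
that detects the phenotype dichotomy, extracts the expression signature, links
genotype to overall growth, tests the functional coherence of top-associated
genes, and scores human cell-line expression against drug resistance — plus a
synthetic-data module that plants every one of those structures with recorded
ground truth so each stage is testable without any external download.

# Phenome preprocessing and low-rank reconstruction

Input is a strains × conditions growth matrix, possibly with missing cells.
Preprocessing is a fixed pipeline, and each stage refuses input that skipped
the previous one:

1. `filter_missing()` — rows, then columns, with more than 10% missing values
   are removed, iterating to a fixed point. The iteration makes the outcome
   order-insensitive (dropping a bad row can rescue a column).
2. `impute_knn()` — each missing cell is filled with the column average over
   the `k = 10` nearest rows. Distance is root-*mean*-square difference over
   mutually observed columns, i.e. Euclidean distance rescaled by the number of
   shared columns, so rows with different missingness patterns are comparable;
   rows sharing no observed column are excluded as neighbours, and a cell with
   fewer than `k` usable neighbours falls back to the column mean with a
   warning.
3. `standardize_conditions()` — every condition column is centred and scaled
   to unit variance. We use the sample (n−1) variance convention.
4. `svd_reconstruct(rank = 2)` — the matrix is reconstructed from its two
   leading singular triplets. Rank 2 keeps the overall-growth axis and the
   trade-off axis while discarding condition-specific idiosyncrasies; by the
   Eckart–Young theorem the Frobenius reconstruction error equals the
   root-sum-square of the discarded singular values, which the tests verify
   against 100 random factorizations.

Singular-vector signs are arbitrary in any SVD; we orient every singular pair
so that the largest-magnitude entry of the right-singular vector is positive.
This pins a unique, reproducible decomposition (the reconstruction itself is
orientation-invariant).

# Consensus clustering and PAC

Conditions are clustered by average-linkage hierarchical clustering on
`1 − Spearman` correlation distance. To choose the number of clusters K,
`consensus_cluster()` resamples 80% of conditions and 80% of strains without
replacement 1000 times, reclusters each subsample, and records for each
condition pair the fraction of iterations — among those where both members were
sampled — in which the pair landed in one cluster. That fraction is the pair's
*consensus index*: 1 for pairs that always co-cluster, 0 for pairs that never
do. Normalizing by the co-sampling count (rather than the iteration count)
keeps the index's extremes exact; a pair never co-sampled (probability
\(\approx (1-0.64)^{1000}\) at the defaults) is assigned 0 and reported.

The *proportion of ambiguous clustering* (PAC) for a given K is the fraction of
off-diagonal unordered pairs whose consensus index falls strictly inside the
ambiguity window (0.1, 0.9); the K minimizing PAC is the most robust cluster
number. We use strict inequalities: with 1000 iterations an index of exactly
0.1 or 0.9 is attainable, so the boundary convention must be pinned, and strict
bounds keep the definitional extremes (0 and 1) unambiguous under any window.
PAC ties are reported as ties — `optimal_k()` returns every minimizing K — and
a flag optionally excludes K values whose assignment contains singleton
clusters. Both the raw standardized matrix and the rank-2 reconstruction are
valid inputs; `run_pipeline()` records which was used.

```{r consensus-demo}
ph <- gen_phenome(n_strains = 120, n_conditions = 16, block_sizes = c(8, 8),
                  tradeoff_strength = 5, noise_sd = 0.5, seed = 1)
rec <- svd_reconstruct(standardize_conditions(ph$matrix), rank = 2)
cc <- consensus_cluster(rec$values, K_range = 2:6, n_iterations = 200, seed = 2)
tidy(cc)
autoplot(cc)
```

`cluster_composition_test()` closes the loop at the strain level: a Pearson
chi-squared test (no continuity correction) of cluster membership against
strain clade labels (wild / domesticated / unassigned).

# The recurrent expression signature

Expression matrices come in two dialects. *Relative* (two-colour microarray)
values are already log-ratios against a pooled reference; *absolute*
(RNA-seq / single-channel intensity) values are first gene-wise mean-centred
(`center_genes()`) to put them on the same deviation scale. Both are then
sample-wise zero-centred (`scale_samples()`; no variance scaling). RNA-seq
counts are expected variance-stabilized upstream; a `log2(x + 1)` fallback is
available to callers but no variance-stabilizing transform is implemented here.

The *first eigenarray* is the first left-singular vector of the scaled matrix:
each gene's coordinate on the dominant expression program across samples, its
*gene signature score*. `robust_signature()` stabilizes it: the SVD is repeated
(default 1000 times) after adding i.i.d. Gaussian noise (mean 0, SD 1) to every
value, and a gene is kept as *sign-consistent* only when its score keeps the
same nonzero sign across the unperturbed run and every perturbation. Because
each perturbed SVD again has an arbitrary sign, every perturbed eigenarray is
first orientation-matched to the unperturbed one (flipped when their inner
product is negative; the flip count is retained). The reported score is the
unperturbed eigenarray value — the canonical, deterministic estimate — not a
perturbation average.

Two design choices deserve emphasis:

* **Orientation.** The unperturbed eigenarray is oriented so its
  largest-magnitude gene scores positive; when two signatures are compared or
  integrated, the second is flipped if their Spearman correlation is negative,
  and integration refuses pairs with \(|\rho| < 0.05\) as non-orientable. Without
  a pinned orientation the PS/NS split would be meaningless.
* **Batch integration.** `integrate_datasets()` intersects gene sets and
  removes additive batch structure by per-batch per-gene mean subtraction — a
  location-only adjustment that exactly cancels the additive offsets the
  generator plants and that the analysis contract requires; full
  empirical-Bayes batch correction is deliberately out of scope and pluggable
  upstream.

`integrate_signatures()` keeps genes whose sign agrees in both inputs (after
orientation) and averages their scores; `split_ps_ns()` partitions the
sign-consistent genes into the PS (positive) and NS (negative) sets. The
characterization helpers — `gene_set_score_distribution()` (per-set score
distributions with pairwise two-sided Wilcoxon rank-sum tests, raw p plus
Benjamini–Hochberg adjusted), `correlate_signature_with_measurement()`
(Spearman against any per-gene measurement) and `group_log2fc()` — reproduce
the downstream analyses on whatever gene sets and measurements the caller
supplies.

```{r signature-demo}
ex <- gen_expression(n_genes = 300, n_samples = 60, signature_sd = 3,
                     noise_sd = 0.5, seed = 3)
sig <- robust_signature(scale_samples(ex$matrix), n_iterations = 100, seed = 4)
glance(sig)
sets <- split_ps_ns(sig)
lengths(sets)
```

# Genotype to overall growth: the LOD scan

`overall_growth_pc1()` computes PC1 of the condition-standardized phenome
(equivalently, correlation-matrix PCA; the standardization convention matches
the phenome module) as the overall growth phenotype, sign-oriented so that it
correlates non-negatively with mean growth — "overall growth" should go up
with growth. For each biallelic marker the linkage statistic is

\[
\mathrm{LOD} = -\,n \,\frac{\ln(1 - r^2)}{2\ln 10},
\]

with `r` the Pearson correlation between the 0/1 genotype and the trait over
`n` segregants — identical to `n/2 · log10(SS_tot/SS_res)` of the single-marker
regression, which the tests verify to 1e−9 on 50 random cases. The number of
segregants is always taken from the data, never from a constant.
`permutation_threshold()` supplies the genome-wide significance line: the trait
is permuted across segregants (default 1000 times), the genome-wide maximum LOD
recorded, and the empirical `1 − alpha` quantile returned. Monomorphic markers
are skipped with a warning. Interval mapping, multi-QTL models and
relatedness corrections are out of scope; mixed-model GWA is expected to be run
externally, with its locus p-values consumed by the network module.

```{r qtl-demo}
cr <- gen_cross(n_segregants = 500, n_markers = 300, qtl = list(c(150, 1)),
                noise_sd = 1, seed = 5)
scan <- lod_scan(cr)
thr <- permutation_threshold(cr, alpha = 0.05, n_permutations = 200, seed = 6)
glance(set_scan_threshold(scan, thr))
```

# Functional connectedness of top-associated genes

`gene_pvalue_from_loci()` maps locus-level association p-values to genes: each
gene gets the minimum p over loci overlapping its body by at least one base.
All coordinates are 1-based inclusive (overlap iff `max(starts) ≤ min(ends)`);
BED-dialect input is converted at parse time. `aggregate_pvalues()` combines a
gene's p-values across condition sets — Fisher's method by default, with a
"min" rule available because the aggregation used for the original six GWA
analyses is not specified; the rule in force is recorded by the pipeline and
neither is asserted as canonical.

On a confidence-weighted functional network (STRING-style edge list), the
top-k genes' coherence is measured as the size of the largest connected
component (LCC) of their induced subgraph, keeping only edges with confidence
*strictly* above 0.4 ("higher than 0.4", medium confidence). The null model
draws the same number of genes uniformly from the network's node universe
(where an LCC is computable) 1000 times; the empirical p-value uses the
add-one estimator and can never be 0. `lcc_size_curve()` repeats this along a
ranking, resampling the null independently at each k.

# Drug-resistance scoring

`map_orthologs()` carries the yeast PS/NS sets to human genes (union over a
possibly one-to-many ortholog table; genes landing in both sets are dropped
from both to avoid double counting). `score_cell_lines()` gene-wise
mean-centres a cell-line expression matrix — making the scores invariant to
per-gene constants — and scores each line with the median centred expression
of each set (even-count medians are midpoints of the central pair);
`correlate_with_resistance()` computes, per drug, the Spearman correlation of
the PS, NS and PS−NS scores with a resistance measure such as the GDSC
Z-score (a normalized IC50; higher = more resistant), pairwise-deleting
missing entries per drug and skipping drugs with fewer than 10 usable lines.
`summarize_correlations()` condenses the per-drug correlations into medians,
quartiles and a sign test.

# The synthetic-data module

The generators are first-class, tested code and define the conditions under
which every downstream claim is checked:

* `gen_phenome()` plants the two-block trade-off: strain axis
  \(a_s \sim N(0,1)\), cell value \(\pm\,\text{strength}\cdot a_s + N(0,\sigma^2)\)
  with the sign set by the condition block, missing cells completely at
  random. Clade labels derive from the latent axis (above +0.5 domesticated,
  below −0.5 wild, else unassigned) so composition tests have plantable
  structure.
* `gen_expression()` plants one dominant two-arm signature
  (\(g_i t_j\) + optional per-batch per-gene offsets + noise); the absolute
  dialect adds a positive per-gene baseline (uniform 5–15, a plausible
  log-intensity scale).
* `gen_cross()` plants additive QTLs on unlinked fair-coin markers — the LOD
  statistic is per-marker, so no recombination map is needed to test it.
* `gen_network()` plants one connected module (random spanning tree plus as
  many extra internal edges) at high confidence over an Erdős–Rényi
  background; gene intervals tile a synthetic chromosome (1 kb genes spaced
  1 kb apart) so locus–gene intersection tests are deterministic.
* `gen_drug_panel()` plants resistance as a monotone function of each cell
  line's NS-minus-PS latent state.

Missingness is uniform completely-at-random — real phenomes have structured
missingness, but the 10% filters only respond to rates. The generators do not
attempt realistic platform noise (no microarray spatial artifacts, no
overdispersed counts), so passing tests demonstrate correctness of the
*methods* under their stated models, not robustness to every real-data
pathology. Ground truth is written to a separate `.truth.json` side-channel
that no pipeline stage reads; `run_pipeline()`'s manifest records every input
each stage consumed.

# Numerical choices and degenerate inputs

* Zero-variance conditions, constant traits, monomorphic markers, empty
  PS/NS arms, empty gene intersections, and sub-minimum overlaps all raise
  informative errors rather than propagating NaNs; top-singular-pair
  degeneracy (gap ≤ 1e−9, relative) makes the eigenarray non-identifiable and
  is refused.
* Ties: Spearman correlations use midranks; `top_genes()` breaks p-value ties
  lexicographically by gene id and reports ties spanning the cutoff;
  equal-distance merges in `hclust` follow its deterministic agglomeration
  order.
* Determinism: every stochastic routine takes an explicit seed;
  `run_pipeline()` derives per-stage seeds as
  `seed · 131 + sum(utf8ToInt(stage))` folded into the 32-bit range, so adding
  a stage never perturbs another stage's stream.
* p-value aggregation clamps p = 0 to the smallest positive double (with a
  warning) before taking logs.

# Problem sizes used in the checks

The automated checks run the full procedures at reduced but structurally
faithful sizes chosen to exercise every code path with comfortable margins:
consensus clustering at 200 strains × 20 conditions with 1000 resampling
iterations; signature recovery at 500 genes × 100 samples with 100
perturbations; the LOD scan at 1008 segregants × 1000 markers with 1000
permutations; the LCC null at 1000 genes with 1000 draws; drug scoring at 100
cell lines × 50 drugs. At these sizes the planted effects sit far from the
decision boundaries (e.g. recovery correlations above 0.95 where 0.9 would
do), so the checks are sensitive to implementation defects rather than to
sampling luck.

# Known limitations

* The consensus-resampling and noise-perturbation loops are plain R; at the
  scale of thousands of genes × thousands of samples with 1000 iterations a
  practitioner would want a truncated SVD and parallel iterations.
* Batch adjustment is location-only; multiplicative batch effects require an
  upstream empirical-Bayes correction.
* Gene-level p-values inherit the resolution of the supplied loci; linkage
  disequilibrium between loci is not modelled.
* Ortholog mapping is a set union; paralog-aware weighting is left to the
  caller's table.
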