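---
title: "Methods: molecular subtyping of PDAC expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular subtyping of PDAC expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacsubtype)
```

`pdacsubtype` implements the analysis chain used to define molecular
subtypes of pancreatic ductal adenocarcinoma (PDAC) from bulk RNA-seq:
unsupervised class discovery, construction of a gene-signature classifier,
concordance analysis between subtyping systems, species-split analysis of
patient-derived xenografts (PDXs), and the supporting survival and clinical
statistics. This vignette documents the models, the parameters that matter,
the numerical conventions, and what the synthetic cohorts do and do not
establish.

## Expression preprocessing

Inputs are genes × samples matrices on the log2 RPKM scale. `rpkm_log2()`
computes `log2(10^9 · c / (L · N) + 1)` from counts `c`, gene length `L`
(bp) and library size `N`; the pseudocount of 1 keeps zero counts at
exactly 0 and is exposed as an argument. A zero library size is an error —
there is no expression level to compute for such a sample.

Gene retention follows the discovery convention: mean log2 RPKM > 1 and
median absolute deviation > 0.5 across samples. The MAD here is the **raw**
median of absolute deviations from the gene median, without the 1.4826
Gaussian consistency factor; the threshold of 0.5 is conventionally quoted
against the raw statistic. `scaled_mad = TRUE` switches to the scaled
variant for users whose thresholds assume it. Medians use R's midpoint
convention for even sample counts. Retained genes are median-centered
(idempotent, shift-only).

Batch adjustment (`batch_correct()`) is the parametric empirical-Bayes
location-scale scheme (ComBat, via `sva`). Consequences of the EB shrinkage
worth knowing: a single batch returns the input unchanged; a batch of one
sample is an error because its scale is undefined; and a constant
between-batch shift is removed only up to shrinkage noise — per-gene
residuals of order 0.1 log2 units at 50 samples per batch are expected, not
a defect. Constant-variance genes are passed through untouched.

## Class discovery

Samples are clustered by average-linkage agglomerative clustering on
`1 − Pearson correlation` between sample profiles. The distance is a design
choice (correlation distance is the field's default for expression
subtyping because it ignores per-sample scale); Euclidean distance is
available via `distance = "euclidean"`. Determinism relies on `hclust`'s
fixed agglomeration order for tied distances.

**Consensus clustering** (`consensus_cluster()`) repeats the clustering on
random subsamples (defaults: 1000 iterations, 95 % of samples drawn without
replacement, both the discovery convention) and records, for each sample
pair, the fraction of co-sampled iterations in which it co-clusters. The
consensus matrix has unit diagonal; a pair never co-sampled (essentially
impossible at 95 % subsampling) is defined as 0 with a warning. Final
labels cut an average-linkage tree of `1 − consensus`. Stability across k
is summarised by the CDF of off-diagonal consensus values and the
delta-area curve: `A(2)` for the first k, `(A(k) − A(k−1))/A(k−1)`
thereafter — the usual consensus-clustering convention.

**Gap statistic** (`gap_statistic()`): for each k,
`W_k = Σ_clusters Σ_{i,i' ∈ cluster} d²_{ii'} / (2 n_cluster)` (the
double-sum convention; `cluster::clusGap` with `d.power = 2` differs by a
constant factor 2 that cancels in the gap), and
`Gap(k) = mean_b log W*_kb − log W_k` over `n_refs` reference datasets
drawn uniformly over the bounding box of the samples after PCA rotation
(the recommended reference; the raw box is available). The standard error
carries the `sqrt(1 + 1/B)` factor, and the selected k is the smallest with
`Gap(k) ≥ Gap(k+1) − se(k+1)`, falling back to the argmax if the inequality
never holds. Degenerate input (all samples identical) short-circuits to
k = 1. Within the gap computation the clustering uses Euclidean distance by
default, matching the uniform-box null; the correlation variant is exposed.

## Signature construction and classification

For each subtype, a one-vs-rest **SAM** test computes
`d_i = (x̄_B − x̄_A) / (s_i + s_0)` with the equal-variance pooled standard
error `s_i` and the fudge factor `s_0` chosen among 5 %-percentiles of
`s_i` to minimise the coefficient of variation of the within-bin MAD of `d`
across 100 `s`-quantile bins. The null is label permutation (default 1000;
all distinct assignments are enumerated when fewer exist). Permutation
subsets are drawn at the smaller group size and complemented, which makes
q-values exactly invariant under label flips. The per-gene q-value is the
median permutation count of statistics at least as extreme divided by the
observed count (π₀ = 1, conservative), monotonised so a larger |d| never
has a larger q.

Genes with q below `fdr_max = 0.01` are ranked by **two-sided AUC
discriminativeness** `max(AUC, 1 − AUC)` (Mann-Whitney identity, ties
counted ½) and the top 40 per subtype retained; ties at the boundary break
by smaller q, then gene id. The ranking direction was an open choice; the
two-sided form was adopted so that low-expression markers count. A
consequence explored in the acceptance suite: a marker planted "up" in two
subtypes competes with other subtypes' down-markers and the per-class lists
can overlap, so the deduplicated union is ≤ 4 × 40 and typically just
under it.

The classifier is **nearest shrunken centroids**: standardized class
offsets `d_kj = (x̄_kj − x̄_j) / (m_k (s_j + s_0))` with
`m_k = sqrt(1/n_k − 1/n)` (the variance factor of a class centroid around
the overall centroid) and `s_0` the median pooled within-class SD, soft-
thresholded at Δ. Δ is selected on a 30-point grid by stratified
cross-validation (default 5 folds), taking the **smallest** Δ among error
ties. Classification uses the Gaussian discriminant
`δ_k(x) = Σ_j (x_j − x̄'_kj)² / (s_j + s_0)² − 2 log π_k` with empirical
priors `π_k`, and posteriors `∝ exp(−δ_k/2)` computed with max-subtraction
for numerical stability; posteriors always sum to 1.

Cross-platform application (`cross_platform_prepare()`) intersects gene
universes and median-centers each cohort per gene. Centering is not part of
the shared-gene convention itself but is required for scale comparability
between platforms; it can be disabled. `gene_set_zscore()` summarises a
gene set per subtype as the mean row-standardized expression over the set,
scaled by the square root of the effective (deduplicated, intersected) set
size; constant genes contribute zero.

## Concordance between subtyping systems

For two labelings over a shared sample universe (samples missing from
either system are dropped pairwise), every cross-system subtype pair is
tested by the upper-tail hypergeometric probability `P = Pr[X ≥ x]`
including the observed overlap — the overrepresentation convention.
Benjamini-Hochberg correction is applied over **all** cross-system pairs as
one family when building the network (the more conservative reading;
per-system-pair families are available for heatmap-style summaries). The
network keeps edges with adjusted P < 0.001, weighted by the Jaccard
coefficient of the two sample sets (`|A∩B| / |A∪B|`; two empty sets give 0
with a warning). Nodes carry subtype prevalence. Exports: edge-list TSV and
GraphML with `prevalence` and `jaccard` attributes.

## PDX compartment analysis

PDX inputs are species-assigned count vectors per xenograft (read-level
assignment is upstream of this package). `combine_expression()` adds each
human gene's counts to those of its best mouse homolog — one-to-one pairs
preferred, then highest identity; duplicate mouse targets are reused with a
warning — normalises each sample to reads per million and returns
`log2(RPM + 1)`. `compartment_expression()` gives the two sides separately
on the homolog-mapped gene universe; restricting to mapped genes matters,
because an unmapped human gene is indistinguishable from a tumor-exclusive
one.

Donor–PDX concordant genes come from a correlation-of-correlations: each
gene's correlation profile against all other shared genes is computed
within donors and within PDXs (self-correlations excluded), the two
profiles correlated, and genes kept with coefficient > 0.25, then further
restricted to SD > 1.7 in **both** datasets.

Compartment-specific genes apply the published min/max rules literally:
epithelial if `(min.ep > 1.5 & max.str < 1.5 & min.ep − max.str > 1.25)` or
`min.ep − max.str > 5`; stromal analogously with a second clause that, as
printed, reads `min.ep − max.str > 8`. That clause is asymmetric — it can
only fire for strongly epithelial genes, which then match both rule sets
and are dropped as conflicts — and looks like a transcription slip for
`min.str − max.ep > 8`. Both behaviours are implemented
(`stromal_rule = "as_written"` is the default; `"symmetric"` is the
corrected form); the as-written default is deliberate: silently "fixing" a
published rule would make results irreproducible against it.

`compartment_normalize()` counteracts tumor/stroma dilution by shifting
each sample (log2 scale) so its mean over the compartment gene set equals
the cohort mean of that set — a location-only interpretation of
anchor-based normalization, recorded as such. The mesenchymal-vs-rest
classifier is a linear-kernel SVM (cost 1 by default) with probability
scores from a Platt-style sigmoid fit to the training decision values with
smoothed targets; fitting the calibration ourselves keeps scores
deterministic and exactly mirrored under label flips. An
`exclude_samples` argument removes, e.g., PDX-donor patients from
training to avoid leakage.

## Survival and clinical statistics

Kaplan-Meier curves use the product-limit estimator with the median defined
as the first time S(t) ≤ 0.5 (`NA` when never reached); with no censoring
the estimator equals the empirical survival function, and all-censored
input is legal (S ≡ 1). A `follow_up` argument applies administrative
censoring (e.g. 24 months for a 2-year analysis window). The log-rank test
is the standard unweighted statistic; Cox regression uses the partial
likelihood with Efron tie handling (the lower-bias default) and Wald
intervals, erroring after 100 Newton iterations without convergence.
Pearson chi-square tests carry no continuity correction, and contingency
tables keep "unknown" rows as ordinary categories by default — the
published per-subtype clinical tables reproduce their printed P-values only
under that convention (`drop_unknown = TRUE` reverses it). Group tests are
the standard ANOVA, Kruskal-Wallis, pooled-variance t (Welch optional) and
Mann-Whitney U.

## The synthetic cohort generator

`simulate_cohort()` draws per-gene baselines N(2.5, 1.5²) on the log2 RPKM
scale, adds i.i.d. Gaussian noise (`noise_sd`, default 1 log2 unit), plants
disjoint per-subtype signature blocks as additive shifts
(`signature_effect`, default 3 log2 units — a strong, unambiguous subtype
signal), assigns samples to subtypes near-uniformly, and adds an additive
location shift per sequencing batch (default 3 batches, 0.5 log2 units).
Survival is exponential per subtype with medians 14.7, 31.8, 21.5 and 14.0
months — the minimal parametric model matching one stated median per
subtype — with independent censoring at rate `censor_rate` (default 0.1;
censored samples report a uniform fraction of their latent time).
`plant_gene_shift()` adds or removes single planted shifts, which is how
overlapping signatures are constructed. `simulate_pdx_pairs()` draws a
human read fraction per xenograft (default U(0.5, 0.9)), splits each shared
gene's expected counts exactly by that fraction before integer rounding,
pins compartment-exclusive markers to one side at a controlled abundance
(10–40 RPM) so they fall inside the selection-rule bands, and emits the
homology table; `count_noise_sdlog = 0` gives the noise-free setting used
for exact-recovery checks. `simulate_alternative_labeling()` degrades a
labeling with a given agreement and renames its vocabulary to emulate an
independent subtyping system.

What the generator does **not** emulate: count overdispersion and
mean-variance coupling, correlated gene modules outside the planted
blocks, compositional effects of library-size normalization, non-additive
batch effects, subtype-imbalanced cohorts, and non-exponential survival.
Passing tests therefore demonstrate correctness of the machinery and
recovery under the stated generative assumptions — not classifier
performance on real tumors.

## Problem sizes and reproducibility

The test and acceptance workloads run at deliberately reduced scale chosen
to keep the full analysis chain exercised: discovery cohorts of 90 samples
× 1000–2000 genes with 40-gene signatures (gap statistic at 50 references,
consensus at 250 iterations, modal-k checks over 10 seeds), classifier
recovery on a 180-sample cohort at the 8000-gene default, concordance
networks at 400 samples over 20 seeds, PDX batches of 14 xenografts × 4000
genes, and Cox recovery at n = 500. All randomness flows from a single
seed: pipeline stages receive deterministically derived sub-seeds, so a
fixed seed yields bit-identical labels, signatures and network edge lists
across runs, which the acceptance script verifies by checksum.

## Known limitations

* The EB batch correction assumes roughly balanced, multi-sample batches;
  singleton batches are rejected rather than approximated.
* SAM's conservative π₀ = 1 slightly inflates q-values; at the 0.01
  threshold with planted effects this costs little sensitivity.
* The PAM threshold search is grid-based; between-grid optima are not
  interpolated.
* Correlation-of-correlations scales quadratically in genes; restrict to a
  filtered universe for large panels.
* The concordance network tests marginal subtype pairs; it does not model
  three-way dependencies between systems.
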