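# pdacsubtype

Molecular subtyping of pancreatic ductal adenocarcinoma (PDAC) from bulk
RNA-seq expression, as an end-to-end, testable R pipeline.

PDAC cohorts harbour transcriptomic subtypes with very different outcomes,
but the analyses that establish them — consensus clustering, cluster-number
statistics, signature classifiers, cross-study concordance, xenograft
compartment splitting, survival models — are usually scattered across
scripts. `pdacsubtype` packages that whole workflow for computational
oncologists who want to discover subtypes in their own cohort, port a
subtype classifier across platforms, or quantify how a new subtyping scheme
relates to existing ones. A synthetic-cohort generator reproduces the
statistical structure the analysis assumes (latent subtypes, planted
signature genes, batch effects, subtype-linked survival, species-split PDX
counts), so every stage is exercised end to end without patient data.

## What is implemented

* **Preprocessing** — counts → log2 RPKM (`rpkm_log2()`), retention of genes
  with mean log2 RPKM > 1 and raw median absolute deviation > 0.5
  (`filter_genes()`), per-gene median-centering, ComBat batch adjustment
  (`batch_correct()`), PCA diagnostics.
* **Class discovery** — average-linkage hierarchical clustering on
  1 − Pearson correlation; consensus clustering over subsampled replicates
  (default 1000 iterations, 95 % subsampling) with CDF/delta-area stability
  curves; the gap statistic for k = 1…8,
  `Gap(k) = mean_b log W*_kb − log W_k`, with reference data drawn uniformly
  over the PCA-aligned bounding box and
  `optimal k = min{k : Gap(k) ≥ Gap(k+1) − se(k+1)}`.
* **Signature classifier** — per-subtype one-vs-rest SAM
  (`d_i = (x̄_B − x̄_A)/(s_i + s_0)` with permutation FDR), two-sided AUC
  ranking with a top-40 cut per subtype, and a nearest-shrunken-centroid
  (PAM) classifier with cross-validated shrinkage and Gaussian-discriminant
  posteriors; `cross_platform_prepare()` harmonises external cohorts on
  shared genes.
* **Concordance** — upper-tail hypergeometric enrichment between subtyping
  systems, Benjamini-Hochberg adjustment, and the Jaccard-weighted subtype
  network (`build_network()`, edges kept at BH-P < 0.001).
* **PDX compartments** — species read fractions, homolog-merged combined
  expression (log2 RPM), donor–PDX correlation-of-correlations gene
  selection (coefficient > 0.25, SD > 1.7 in both), the literal
  epithelial/stromal min–max selection rules, compartment-anchored
  normalization, and linear-kernel SVM mesenchymal classifiers with
  Platt-calibrated probability scores.
* **Survival & clinical statistics** — Kaplan-Meier, log-rank, multivariate
  Cox (Efron ties), Pearson chi-square (with "unknown" as an ordinary
  category), ANOVA/Kruskal-Wallis/t/Mann-Whitney, and the published
  per-subtype contingency tables (`pdac_clinical_tables()`).
* **Orchestration** — `run_pipeline(pipeline_config(...))` chains
  simulate → preprocess → discover → signature → classify → concordance →
  pdx → survival with one master seed and writes TSV/GMT/JSON/GraphML
  artifacts; results carry broom-style `tidy()`/`glance()` methods and
  ggplot2 `autoplot()`s.

## Worked example

```r
library(pdacsubtype)

cohort <- simulate_cohort(cohort_spec(n_samples = 90, n_genes = 2000, seed = 7))
expr <- filter_genes(cohort$expression)
expr <- batch_correct(expr, setNames(cohort$clinical$batch,
                                     cohort$clinical$sample_id))
expr <- median_center(expr)

gap <- gap_statistic(expr, k_range = 1:8, n_refs = 50, seed = 7)
glance(gap)
#> # A tibble: 1 × 2
#>   optimal_k   n_k
#> 1         4     8

cons <- consensus_cluster(expr, k_range = 2:6, iterations = 250, seed = 7)
labels <- cons[["k=4"]]$labels

sig <- build_signature(expr, labels, n_permutations = 300, seed = 7)
length(sig)
#> [1] 155

model <- train_centroid_classifier(expr, labels, sig, cv_folds = 5, seed = 7)
pred <- classify(model, expr)
head(pred, 3)
#> # A tibble: 3 × 6
#>   sample_id label       C1       C2       C3       C4
#> 1 S001      C1    1   e+ 0 2.29e-29 8.63e-33 8.34e-33
#> 2 S002      C2    9.21e-32 1   e+ 0 2.80e-43 6.48e-37
#> 3 S003      C2    1.40e-34 1   e+ 0 1.03e-43 7.41e-41

surv <- dplyr::mutate(cohort$clinical,
                      group = pred$label[match(sample_id, pred$sample_id)])
logrank_test(surv)
#> # A tibble: 1 × 3
#>   statistic    df p_value
#> 1      15.0     3 0.00179
glance(km_estimate(surv))
#> # A tibble: 4 × 4
#>   group     n events median
#> 1 C1       23     19   34.7
#> 2 C2       22     19   13.5
#> 3 C3       22     21   11.4
#> 4 C4       23     22   24.7
```

The gap statistic recovers the four planted subtypes; the discovered
clusters carry a 155-gene signature (at most 4 × 40 with shared markers
deduplicated); posteriors are essentially 0/1 at this planted effect size;
and the subtype-stratified log-rank test picks up the subtype-linked
survival differences built into the generator (one long-lived subtype at
~32 months median, the others much shorter).

Clinical association example on the published per-subtype counts:

```r
pearson_chisq(pdac_clinical_tables()$radicality)
#> # A tibble: 1 × 3
#>   statistic    df p_value
#> 1      10.7     3  0.0133
```

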