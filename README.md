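# ipfsubsets

Idiopathic pulmonary fibrosis (IPF) is not one disease at the molecular
level: lung transcriptomes of IPF patients split into reproducible subsets —
one enriched for myeloid-cell gene expression, the other for ciliated
epithelium and B/plasma-cell programs. `ipfsubsets` implements, as a tested
and reusable R pipeline, the full computational chain for discovering and
characterising such patient subsets from bulk and single-cell lung
transcriptomes. It is written for computational biologists who want to run,
audit or extend each stage of that chain on their own cohorts — or on the
package's synthetic cohorts with planted ground truth, which make every
stage testable without any data download.

## What the package computes

1. **Minimal cell-type signatures** from annotated single-cell RNA-seq.
   For each cell type, genes are ranked by one-vs-rest differential
   expression (Wilcoxon rank-sum on log-normalized counts, effect
   `log2((mean_in + 1)/(mean_out + 1))`, BH-FDR ≤ 0.05). The signature is
   the shortest ranking prefix whose gene-set AUROC is within ε = 0.005 of
   the best prefix AUROC, with a minimum of 5 genes
   (`build_all_signatures()`).
2. **GSVA enrichment scores**, implemented from first principles
   (`gsva_scores()`): per-gene kernel CDF across samples
   (Gaussian kernel, bandwidth `sd/4`), within-sample ranking with
   symmetric rank weights `|p/2 − r|^τ`, and a weighted
   Kolmogorov–Smirnov-like random walk per gene set; scores lie in [−1, 1].
3. **Consensus clustering with PAC model selection**
   (`consensus_cluster()`): repeated 80 % subsampling, average-linkage
   hierarchical clustering on 1 − Pearson correlation over the most
   variable genes, co-clustering frequencies per sample pair, and the
   Proportion of Ambiguous Clustering `PAC = F(u2) − F(u1)` to pick `k`
   (lower is crisper; the stratification analyses force `k = 2`).
4. **Subset statistics**: covariate-adjusted per-gene OLS differential
   expression with BH FDR (`differential_expression()`), cross-cohort
   log-fold-change replication (|logFC| > 0.58, FDR < 0.05;
   `logfc_replication()`), and Kruskal–Wallis + Dunn post-hoc comparisons
   of signature scores (`score_group_test()`).
5. **Ligand–receptor inference** on donors split by ciliated-cell fraction
   (20 % cutoff): expression-gated mean-product interaction strengths with
   a label-permutation z-score and add-one p-value
   (`score_lr_interactions()`), filtered to the top decile.
6. **Subset classifiers**: stratified 70/30 split, 5-fold CV, three model
   families (elastic-net logistic, linear SVM, gradient boosting) and
   recursive feature elimination (`fit_and_evaluate()`,
   `recursive_feature_elimination()`).
7. **Drug-response signature scoring**: union of drug-downregulated genes
   at |logFC| ≥ 1.41, p < 0.05 (`combine_drug_response_genes()`), scored by
   GSVA and compared across subsets.

A synthetic-cohort generator (`sim_config()`, `simulate_single_cell()`,
`simulate_bulk_cohort()`, `simulate_replication_cohorts()`) plants a
six-archetype lung with marker genes, two patient subsets defined by
cell-type composition shifts, covariates and replication structure, and
returns the ground truth alongside the data.

## Worked example

```r
library(ipfsubsets)

cfg  <- sim_config(seed = 1)                    # 2000 genes, 60 cases + 30 controls
sc   <- simulate_single_cell(cfg)
sigs <- build_all_signatures(sc$dataset)
glance(sigs)
#>   cell_type    n_genes achieved_auroc max_prefix_auroc
#> 1 bcell_plasma       6          0.997                1
#> 2 ciliated           6          0.997                1
#> 3 endothelial        5          0.997                1
#> 4 fibroblast         6          0.997                1
#> 5 myeloid            5          0.996                1
#> 6 tcell              5          0.997                1
```

Each cell type is captured by 5–6 genes whose combined score separates it
from all other cells with AUROC ≈ 0.997. Projecting the signatures onto a
bulk cohort and clustering the cases:

```r
bulk   <- simulate_bulk_cohort(cfg, seed = 2)
scores <- gsva_scores(bulk$expr, as_gene_sets(sigs))
cases  <- bulk$metadata$sample_id[bulk$metadata$diagnosis == "case"]
cons   <- consensus_cluster(select_top_variable_genes(bulk$expr[, cases], 500),
                            consensus_params(k_range = 2:4, n_resamples = 250, seed = 1))
glance(cons)
#>       k    pac chosen
#> 1     2 0.0638 TRUE
#> 2     3 0.220  FALSE
#> 3     4 0.163  FALSE
```

`k = 2` has by far the lowest PAC (0.064): the cohort splits into two crisp
classes, which agree with the planted subsets at ARI = 0.93. The signature
scores then recover the planted biology — myeloid scores higher in class 1,
ciliated scores higher in class 2:

```r
labels <- consensus_labels(cons, 2)
groups <- ifelse(bulk$metadata$diagnosis == "control", "control",
                 paste0("class", labels[bulk$metadata$sample_id]))
score_group_tests(scores[c("myeloid", "ciliated"), ], groups) |>
  dplyr::filter(group_a == "class1", group_b == "class2")
#>   signature kw_statistic     kw_p group_a group_b dunn_z        p    adj_p
#> 1 myeloid           61.7 3.90e-14 class1  class2    7.83 5.04e-15 1.51e-14
#> 2 ciliated          60.5 7.45e-14 class1  class2   -7.06 1.64e-12 4.91e-12

fit_and_evaluate(t(scores[, cases]), labels[cases],
                 classifier_spec("elastic_net_logistic", seed = 1))
#> elastic_net_logistic: validation AUROC 1.000 (CV 1.000 +/- 0.000)
```

`run_end_to_end(cfg, out_dir = "out")` chains all eight stages and writes
TSV/GMT/JSON outputs plus a manifest with every seed and parameter.

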