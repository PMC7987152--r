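---
title: "Stratifying pulmonary fibrosis transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying pulmonary fibrosis transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfsubsets)
```

`ipfsubsets` chains six analysis stages — cell-type signature derivation,
GSVA projection, consensus clustering, subset statistics, ligand–receptor
inference and classification — into a pipeline for stratifying idiopathic
pulmonary fibrosis (IPF) lung transcriptomes. This vignette is the
package's account of the science in each stage: the model, its
assumptions, the parameters that matter, and the design decisions taken
where the method left genuine room for choice.

## Minimal cell-type signatures

The premise is that bulk lung expression shifts between patient subsets
largely reflect shifts in cell-type composition, and that a small set of
marker genes per cell type suffices to track them. Given single-cell
counts with annotated cell clusters, `rank_markers()` contrasts one
cluster against all other cells per gene, and `select_minimal_signature()`
finds the smallest prefix of that ranking which discriminates the type.

**Marker ranking.** Counts are log-normalized as
`log2(1 + 1e4 · count / cell_total)`. Each gene gets a two-sided Wilcoxon
rank-sum p-value (normal approximation with tie correction and continuity
correction — exact at these cell counts would be both infeasible and
unnecessary), an effect size `log2((mean_in + 1)/(mean_out + 1))` on the
linear normalized scale, and a BH-adjusted p. Markers with adjusted
p ≤ 0.05 are kept, restricted by default to upregulated genes, because
signatures are consumed downstream as enrichment gene sets where
downregulated members would dilute the signal. A rank-based test was
chosen over a hurdle model deliberately: it is distribution-free, fast for
the ~10⁴ tests per dataset, and the pipeline's conclusions do not hinge on
the DE engine.

**Greedy prefix search.** Prefixes of the effect-sorted ranking are scored
by `gene_set_auroc()`: each cell's score is the mean of gene-wise z-scored
log-normalized expression over the set, and the AUROC of that score for
membership in the target type is the prefix's accuracy. How a *multi-gene*
set should be collapsed to one per-cell score is the largest inference gap
in the procedure — the mean-of-z-scores rule is the package's choice
(simple, scale-free, and symmetric in the genes) and is isolated behind a
single function so alternatives can be substituted. All prefixes up to
`max_genes` (default 200) are evaluated, because "within ε of the maximum"
requires knowing the maximum; the returned signature is the shortest
prefix with AUROC ≥ max − ε, extended to `min_genes` if shorter. Defaults
ε = 0.005 and `min_genes = 5` are the procedure's published operating
point. Zero-variance genes contribute zero to every cell's score, with a
warning, rather than erroring deep inside a batch run.

## GSVA from first principles

`gsva_scores()` re-implements gene set variation analysis rather than
wrapping an existing implementation, since the enrichment statistic is a
core part of what the package exists to provide and to test. The three
steps:

1. **Kernel CDF per gene.** For gene *i* with expression `x` across
   samples, `F̂(x_j) = (1/n) Σ_k Φ((x_j − x_k)/h)` with `h = sd(x)/4`
   (Gaussian kernel, for continuous log-scale data). A Poisson kernel
   (`λ = x_k + 0.5`) is available for integer counts, and a plain
   empirical CDF for testing. Constant genes are dropped with a warning:
   they carry no ranking information and would make `h = 0`.
2. **Within-sample ranking.** Genes are ordered by decreasing kernel CDF;
   the gene at rank `r` receives weight `|p/2 − r|^τ` (τ = 1), so
   extreme-ranked genes dominate and mid-ranked genes are ignored. Ties
   are broken by gene id — the reference implementation leaves this to
   sort stability; a deterministic rule makes runs reproducible.
3. **Weighted random walk.** For a set with `m` genes,
   `ν(ℓ) = Σ_{i≤ℓ, i∈set} w_i / Σ_{i∈set} w_i − #(i≤ℓ, i∉set)/(p − m)`.
   The default score is GSVA's `max_diff`, `max(0, max ν) + min(0, min ν)`;
   `abs_max` (the signed maximum deviation) is kept for sensitivity
   analysis. Both are bounded in [−1, 1] by construction and no rescaling
   is applied afterwards. A set covering all genes is an error (the
   outside-set penalty is undefined); a set whose weights are all exactly
   zero (possible only when every member sits at the midpoint rank) falls
   back to unweighted counting.

With the Gaussian kernel the whole chain is invariant to per-gene positive
affine transforms and to gene order — both are asserted as tests, along
with equality (to 1e-10) against an independently coded literal
transcription of the three steps.

## Consensus clustering and PAC

`consensus_cluster()` repeatedly draws 80 % of samples without
replacement, clusters each subsample, and records for every sample pair
the fraction of co-sampled iterations in which they co-clustered. The base
clusterer is average-linkage hierarchical clustering on 1 − Pearson
correlation (a k-means option exists); the correlation distance is why the
top-variable-gene filter matters — `select_top_variable_genes()` keeps the
genes (5,000 on full-size cohorts; unbiased sample variance, ties broken
by gene id) whose between-sample differences carry the subset signal.
Final labels per `k` come from re-clustering `1 − consensus`. Pairs never
co-sampled (vanishingly rare at 1,000 resamples) get consensus 0 with a
warning.

Model selection uses the Proportion of Ambiguous Clustering:
`PAC = F(0.9) − F(0.1)` over the off-diagonal upper-triangle consensus
entries, with weak inequalities at both endpoints (boundary conventions
differ between implementations, so ours is documented and tested against
closed forms: a {0,1}-valued matrix has PAC 0, an all-0.5 matrix PAC 1).
`choose_k()` returns the PAC argmin with ties to the smallest `k`; the
stratification analyses override to `k = 2` regardless, trading a possibly
lower PAC at larger `k` for interpretable, well-powered two-class
comparisons.

## Subset statistics

Differential expression between subsets is per-gene ordinary least squares
on a group indicator plus covariates (smoking and gender in the cohort
design), with a two-sided t-test on the group coefficient and BH FDR.
Empirical-Bayes variance moderation is intentionally not applied: at 30+
samples per subset the moderation changes little, and an unmoderated fit
is exactly reproducible with `stats::lm` — which the tests exploit as an
oracle. Genes with zero residual variance are flagged `degenerate` rather
than silently producing NaNs.

Replication across cohorts filters both DE tables to |log2FC| > 0.58 and
FDR < 0.05 (strict inequalities, as the thresholds are exclusive bounds),
intersects the surviving genes and reports the Pearson correlation of the
log-fold-change vectors.

Signature scores are compared across groups with a Kruskal–Wallis omnibus
test followed by Dunn's rank-based pairwise z with tie correction, BH
adjusted within each signature's family of contrasts (not across
signatures — the families are separate questions). The omnibus test is
Kruskal–Wallis rather than a parametric ANOVA because Dunn's test is
defined on the pooled ranks; pairing it with a parametric omnibus would be
internally inconsistent.

## Ligand–receptor inference

Donors are split by their summed ciliated-cell fraction at 20 %; the
boundary value goes to `Ciliated_high` (the published split defines only
strict inequalities, leaving the measure-zero boundary to convention).
Interaction scoring is a declared stand-in with a fully specified
contract, since the upstream tool's internal scheme is not published: a
ligand–receptor pair contributes an edge from sender to receiver type when
both genes are expressed (nonzero in ≥ 10 % of the type's cells — a common
single-cell convention); the strength is the product of mean log-normalized
expressions; the null is obtained by shuffling cell-type labels
(n = 1,000 by default), giving a z-score and an add-one permutation
p-value that can never be exactly zero. The top decile by z (ties at the
threshold kept) forms the reported network. The whole scheme sits behind
one function so a different inference engine can be swapped in.

## Classifiers

The classification protocol — stratified 70/30 split, 5-fold CV on the
training split for hyperparameter choice, held-out AUROC on the 30 % — is
the bespoke logic; the model internals delegate to `glmnet` (elastic-net
logistic, α = 0.5), `e1071` (linear-kernel SVM) and `xgboost` (gradient
boosting, exact split finding — the histogram method places thresholds on
training values, which at these sample sizes misranks boundary validation
samples). The published protocol leaves ambiguous whether CV ran on the
training or validation portion; CV-on-train with a untouched 30 % holdout
is the defensible reading and is what is implemented. Recursive feature
elimination drops the lowest-importance half of remaining features per
round and declares the minimal set as the smallest size within 0.005 CV
AUROC of the best — reusing the signature-search ε for internal
consistency, as no RFE stopping rule is published.

## The synthetic cohorts

`sim_config()` defines the study conditions for every test and for the
acceptance script. The generator emulates:

* a six-archetype lung — myeloid, ciliated epithelium, B/plasma, T,
  endothelial, fibroblast — with 20 disjoint marker genes per type at
  log2 fold change 3 over a negative-binomial baseline
  (mean 0.5, size 2) for single-cell counts;
* two planted patient subsets plus controls (30 donors each, 2,000 genes
  in bulk): bulk expression is `log2(1 + Σ_t p_t · profile_t)` plus
  covariate effects and Gaussian noise (sd 0.25), with per-sample
  proportions `p` drawn Dirichlet around the group's composition vector
  (concentration 50 — moderate inter-donor variability). Subset 1 doubles
  the myeloid fraction (0.40 vs 0.20 in controls); subset 2 triples
  ciliated (0.30), doubles B/plasma (0.20) and depletes T cells (0.08),
  mirroring the qualitative direction of the published subset biology;
* binary smoking/gender covariates (Bernoulli(0.5)) with additive
  N(0, 0.3) effects on a random 10 % of genes, so covariate adjustment in
  DE is actually exercised;
* replication: two cohorts sharing marker map and compositions with
  independent donors and noise.

These sizes keep a full pipeline run under ~10 s while leaving all
downstream effects comfortably detectable but not degenerate. What the
generator does **not** emulate: probe-level microarray artefacts, batch
effects beyond a scalar offset, doublets or ambient RNA in single-cell
data, correlated marker programs across cell types, and continuous
composition gradients between subsets. Passing tests on these cohorts
therefore demonstrate that the machinery recovers planted structure of the
published kind — not that real cohorts contain such structure, nor that
the pipeline is robust to every artefact real data carries.

## Numerical conventions

* AUROC uses the Mann–Whitney form; tied pairs count ½.
* Duplicate gene ids in expression tables collapse by mean (probe
  convention); duplicate sample ids are an error.
* Matrices are gene-major (genes × samples everywhere); ids are
  authoritative, positions are not.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; fixed seed implies byte-identical output.
* Drug-signature filtering treats the 1.41 log-fold-change cutoff as
  inclusive (a "cutoff of 1.41" is read as attainable) and the p cutoff as
  strict; the scale of the threshold is opaque to the package — it filters
  whatever `logfc` column it is given.

## Problem sizes in the test suite

The suite runs the oracle-equivalence checks at 200 instances (signature
search), 1,000 instances (AUROC) and 50 genes × 10 samples × 5 sets
(GSVA); recovery and calibration checks use the default cohort sizes above
with 20 seeds where a success rate is asserted, 250 consensus resamples
over the top 500 variable genes, 2,000 null genes for DE calibration, 500
Kruskal–Wallis null simulations and 499 label permutations for the
ligand–receptor null. These are the package's declared operating sizes for
its own validation and complete in well under the suite's runtime budget
on a single core.

## Known limitations

* The per-cell gene-set score (mean of z-scores) is one defensible choice
  among several; signatures derived under a different aggregation rule may
  differ at the margin.
* The OLS differential-expression engine does not moderate variances; at
  small group sizes (< ~10 per group) moderated engines will be better
  calibrated.
* The ligand–receptor stand-in reproduces the published *outputs*
  (z-scores, decile filtering) under a transparent null, not any specific
  tool's internals.
* With few donors, the 20 % ciliated split is a coarse instrument: a
  single donor near the boundary moves the agreement with planted subsets
  substantially.
* Consensus clustering inherits correlation distance's blindness to
  uniform shifts; signals must live in relative gene differences, which is
  why the variable-gene filter precedes it.
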