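# mitostate

Mitochondria-driven cell-state discovery in kidney single-cell RNA-seq.

Diabetic kidney disease (DKD) perturbs mitochondrial function unevenly
across renal cell types. `mitostate` implements, as one coherent tested
pipeline, a workflow that discovers **health-dominant (HDC)** versus
**disease-dominant (DDC)** cell subpopulations *within* each annotated cell
type by clustering cells on mitochondrial pathway activity, then explains
the two states through exclusive differential genes (ESDEGs), gene-set
enrichment, pseudotime, ligand–receptor communication and a
receptor→TF→target regulatory cascade, and finally connects back to bulk
RNA-seq by deconvolution and label transfer.

## The statistics at the core

* **Per-cell pathway scores** — kernel-CDF random-walk scores
  (per gene *i*, cell *j*: ẑᵢⱼ = mean over cells k of Φ((xᵢⱼ − xᵢₖ)/hᵢ),
  hᵢ = sdᵢ/4; per cell a weighted KS-like walk over the gene ranking with
  weight |rank|^τ, score = max positive + min negative deviation ∈ [−1,1]),
  plus single-sample running-sum scores (weight rank^α, α = 0.25) and
  AUC-of-recovery-curve regulon activity.
* **Moderated differential testing** — empirical-Bayes variance shrinkage:
  posterior s² = (d₀s₀² + d·s²)/(d₀ + d) with (d₀, s₀²) from trigamma
  moment matching; moderated t on d₀ + d df; significant when BH-adjusted
  p < 0.05 and |log2FC| > 0.5.
* **Two-state discovery** — PCA + shared-nearest-neighbour graph (k = 20,
  Jaccard-pruned at 1/15) + modularity clustering at a per-cell-type
  resolution; DDC = cluster whose per-sample cell fractions are
  significantly higher in DKD samples (unpaired t-test).
* **Communication** — probability = l·r/(Kh + l·r) on 25%-trimmed cluster
  means (Kh = 0.5), permutation p with the add-one rule, retention at
  p < 0.05.
* **Cascade** — regression-forest regulons (optional motif prior with the
  NES > 3.0 rule), receptor→TF edges at |Spearman| ≥ 0.3 with BH p < 0.05,
  TF→target edges from regulon membership.
* **Bulk** — TPM, NNLS deconvolution against top-10-marker signatures with
  simplex renormalisation, and 0.8-quantile Spearman label transfer.

A negative-binomial synthetic-data generator with planted ground truth
(two pathway-activity states, doublets, a causal ligand→receptor→TF→target
chain, bulk mixtures, a latent severity ordering) backs every recovery
test. See the methods vignette (`vignettes/mitostate-methods.Rmd`) for the
models, parameter defaults and design decisions.

## Worked example

Simulate a Ctrl/DKD dataset with two planted pathway-activity states and
run the discovery stage:

```r
library(mitostate)

sim <- simulate_dataset(sim_config(seed = 1, n_cell_types = 1,
                                   cells_per_type_per_sample = 30,
                                   n_genes = 300))
sim$counts
#> count_matrix: 339 genes x 240 cells
#>   groups:      Ctrl, DKD
#>   cell types:  Type1

norm   <- normalize_log(sim$counts)
summary(compute_pmem(sim$counts, sim$catalog))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.568   1.108   1.971   2.367   3.644   6.475

scores <- gsva_scores(norm, sim$sets)
grp    <- factor(sim$counts$cell_meta$group, levels = c("Ctrl", "DKD"))
md     <- moderated_diff(scores, grp)
md
#> moderated_diff_result: 60 features, 25 significant (d0 = 47.4)

sig <- md$feature[md$significant]
cl  <- recluster_on_scores(scores[sig, ], dims = 8, resolution = 0.1)
asg <- classify_dominance(cl, sim$counts$cell_meta)
asg
#> subcluster_assignment: 118 DDC / 122 HDC cells
#>   cluster mean_frac_1 mean_frac_2            p   ddc
#> 1       0         0.9   0.1166667 9.627074e-06 FALSE
#> 2       1         0.1   0.8833333 9.627074e-06  TRUE

mean(asg$label == sim$truth$state[names(asg$label)])
#> [1] 1
```

Reading: 25 of 60 pathway sets pass the dual significance rule between the
groups (24 carry the planted shift); re-clustering the cells on those
scores yields exactly two clusters; cluster 1 holds 88% of each DKD
sample's cells but only 10% of each Ctrl sample's (p ≈ 1e-5) and is
labelled DDC; every cell recovers its planted state.

Downstream stages work the same way from these objects: `wilcoxon_de` +
`build_esdeg` for exclusive genes, `fit_pseudotime` on the ESDEG
submatrix, `permutation_test` + `select_dccp` on HDC/DDC-split clusters,
`infer_regulons` + `build_cascade` for the regulatory chain, and
`deconvolve` / `transfer_labels` for bulk integration.

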