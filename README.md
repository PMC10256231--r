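# fieldomics

Statistical toolkit for **single-plant field omics**: trials in which many
individual plants of one genotype grow on a regular grid, each plant's
transcriptome is profiled once, and phenotypes are recorded for every
plant through the season. With no controlled treatments, the signal lies
in each plant's response to micro-environmental variation across the
field — and the analysis must deal with sequencing batches and technical
repeats, spatial autocorrelation, and a feature space (tens of thousands
of genes) that dwarfs the number of plants (~62).

The package implements the full analysis chain, plus a synthetic
field-trial generator with recorded ground truth so every stage can be
validated end to end:

* **Synthetic trials** — grid layout with borders and missing plants; a
  latent micro-environment with Gaussian covariogram
  `Σij = σ²(ν·Iij + (1−ν)·exp(−(dij/r)²))`; negative-binomial counts
  with batch effects, size factors and technical repeats; phenotypes
  driven by known causal genes; beta-sigmoid height series.
* **rlog normalization** — per-gene NB regression
  `k_ij ~ NB(s_j·q_ij, α_i)`, `log2 q_ij = x_j·β_i` with batch fixed
  effects and empirical-Bayes shrunken per-plant effects; the output
  `rlog_ij = β_i0 + β_ip` is batch-corrected and unites technical
  repeats into one value per plant.
* **Spatial statistics** — global Moran's I
  `I = (n/w)·(x−x̄)ᵀC(x−x̄)/‖x−x̄‖²` on queen-contiguity or
  inverse-distance weights, with permutation and parametric nulls, BH
  adjustment, and rank/hypergeometric category tests.
* **Variability** — CVs, a gamma-GLM mean–CV² trend (`CV² = a/x̄ + b`),
  the normalized CV `normCV = log2(CV²/trend(x̄))`, 3-scaled-MAD outlier
  flagging, Shapiro–Wilk + Anderson–Darling normality screens.
* **Growth curves** — beta-sigmoid height fits on growing-degree-day
  time, with analytic maximum growth rate and conversion back to days
  after sowing.
* **Spatial mixed-model association** — `y = β0 + β1x + ε`,
  `ε ~ N(0, σ²·(ν·I + (1−ν)exp(−(d/r)²)))` fitted by REML with Wald
  tests, BH adjustment and an ordinary-regression fallback; conditional
  log-link models for ratio phenotypes with four error structures.
* **Prediction protocol** — 9×10-fold repeated cross-validation with
  three feature selectors (median expression, Spearman, HSIC lasso),
  elastic-net and random-forest learners, pooled metrics, a 90-dataset
  permutation baseline with the 95th-percentile "star" rule, and
  feature-importance ranking.

## A worked example

```r
library(fieldomics)

# a complete synthetic trial: 200 genes, 20 of them a causal module
trial <- simulate_field_trial(sim_config(n_genes = 200, seed = 1))
trial$design
#> Field design: 10 x 10 grid, 0.5 m spacing
#>   positions: 100 (border 36, missing 0, analysis 64)

# normalize: batch effects out, technical repeats united per plant
fit <- rlog_fit(trial$counts, trial$meta)
fit
#> rlog fit: 200 genes, 77 samples, 64 plants, 3 batches (ref b1)
#>   plant-effect prior variance: 0.4526 (log2 scale)
rl <- rlog_matrix(fit)            # genes x plants

# spatial autocorrelation of each gene (queen weights, permutation null)
mor <- moran_screen(rl, trial$design, n_perm = 999, seed = 1)
head(mor[order(mor$p_perm), c("id", "I", "p_perm", "q_perm")], 3)
#>         id         I p_perm      q_perm
#> 1 gene0001 0.3761918  0.001 0.003389831
#> 8 gene0008 0.4415535  0.001 0.003389831
#> 9 gene0009 0.4564280  0.001 0.003389831

# which genes associate with the yield phenotype, spatially aware
co <- analysis_coords(trial$design)[colnames(rl), ]
y  <- trial$phenotypes$yield[match(colnames(rl),
                                   trial$phenotypes$plant_id)]
assoc <- screen_features(y, t(rl), co)
attr(assoc, "n_significant")      # genes with q <= 0.05
#> [1] 74
mean(trial$truth$causal_gene_ids %in%
       assoc$feature[assoc$q <= 0.05])   # causal genes recovered
#> [1] 1

# predict yield from expression: 9x10-fold CV + permutation baseline
pred <- run_repeated_cv(t(rl), y, selector = "median", model = "enet",
                        seed = 0)
pred
#> Repeated CV prediction (median selector, enet model)
#>   median test R2:    0.915  (90 splits)
#>   median pooled R2:  0.924
#>   median pooled PCC: 0.962
```

The Moran screen reports, per gene, the autocorrelation statistic and
its permutation pseudo-p (many genes are spatially structured here,
because they read out the latent micro-environment). The association
screen counts genes whose spatial-LME slope survives BH at 5% — it
recovers all 20 truly causal genes, along with non-causal genes that
track the same micro-environmental factor driving the phenotype, which
is what an association screen on field data should find. The prediction
result shows the held-out phenotypic variance explained, with
`permutation_baseline()` available to judge whether such a score beats
chance.

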