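# domapr — dynamic organellar maps in R

Spatial proteomics by fractionation profiling: cells are lysed, organelles
are partially separated by a short series of differential-centrifugation
spins, and every protein is quantified across the resulting fractions.
Proteins of one organelle co-fractionate, so each protein's normalized
abundance profile across the five fractions places it in the cell. domapr
implements the complete downstream analysis for this kind of experiment —
for proteomics labs running organellar maps and for computational
biologists re-analysing published ones:

* **Import & filtering** — MaxQuant proteinGroups parsing with
  per-fraction quantification stringency (complete 5-ratio profiles,
  ≥ 3 quantification events per fraction or 2 events below 30% ratio
  variability).
* **Maps** — yield-weighted normalized profiles
  `p_j = (w_j/HL_j) / Σ_k (w_k/HL_k)`, PCA visualization, protein
  neighbourhoods (squared Euclidean profile distance), inter-map
  concordance.
* **Classification** — marker-trained RBF-SVM per compartment
  (one-vs-rest, stratified 16-fold CV over a sigma/C grid), cumulative
  combination of replicate maps by summed positive scores, percentile
  confidence scores, subcompartment prediction, organellar/nuclear-balance
  Z-filtering.
* **Translocation detection (MR plot)** — per replicate pair the delta
  matrix `Δ = treated − control`; magnitude
  `M = −log10(Q)` from robust squared Mahalanobis distances
  `d² = (δ−μ̂)ᵀ Σ̂⁻¹ (δ−μ̂)` with μ̂, Σ̂ by minimum covariance determinant,
  `d² ~ χ²(5)` under the null, Benjamini–Hochberg adjusted;
  reproducibility `R` = Pearson correlation of delta profiles between
  replicates; cut-offs calibrated on mock experiments for an empirical
  FDR, with depth scaling `E[FP] = mock hits × depth_exp / depth_mock`.
* **Global distributions & abundance** — nuclear/organellar/cytosolic
  profiles and classes, organelle leakage, LFQ pool-change volcano tests
  with seeded low-intensity imputation, histone proteomic-ruler copy
  numbers (`copies_i = share_i × M_total × N_A / MW_i` anchored to DNA
  mass), copy-change tests, compartment copy flux, and a
  mass-conserving organelle protein-mass budget.
* **Synthetic experiments** — a seeded generator with known ground truth
  (logistic-normal profiles, day batches, injected translocations,
  release-efficiency global fractions, a ruler-consistent histone block)
  that makes every stage testable at desk scale.

## Worked example

A synthetic comparative experiment: 1000 proteins in 8 compartments,
3 control + 3 treated maps, with 5 plasma-membrane proteins moved
completely to endosomes in the treated condition.

```r
library(domapr)
sc <- fraction_scheme()

tr   <- tibble::tibble(from = "Plasma membrane", to = "Endosomes",
                       n = 5, lambda = 1)
spec <- sim_spec(translocations = tr, seed = 42L)
ctrl <- make_map_set(spec)
trt  <- inject_translocations(ctrl)

mr <- detect_translocations(
  lapply(ctrl$maps, normalize_map, scheme = sc),
  lapply(trt$maps,  normalize_map, scheme = sc),
  sc, m_cut = 0.6, r_cut = 0.7
)
sum(mr$significant)
#> [1] 5
setdiff(mr$protein_id[mr$significant], trt$truth$protein_id[trt$truth$moved])
#> character(0)
```

All five injected movers are recovered with no false positives: their M
scores (14–36) sit far above the largest null M (0.008) and their delta
profiles correlate across replicates (R 0.82–0.95). Classification of the
same maps:

```r
model <- train_svm(ctrl$maps[[1]], ctrl$markers, sc, seed = 1L)
glance(model)
#> # A tibble: 1 × 6
#>   sigma     C cv_error n_markers n_compartments cv_folds
#> 1  0.25     8        0        99              8       16
loo_marker_accuracy(ctrl$maps[[1]], ctrl$markers, model)$overall
#> [1] 100
```

`plot_mr(mr)`, `autoplot(pca_project(ctrl$maps, sc), labels = ctrl$markers)`
and `autoplot()` on the LFQ comparison give the standard MR, map and
volcano figures. `run_static()` / `run_dynamic()` chain the full
workflows and `write_bundle()` persists every layer as TSV.

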