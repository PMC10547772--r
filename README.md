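# ramanprom

Prominence-ratio classification of Raman spectra of thyroid tissue.

## What it does and for whom

Raman microspectroscopy of thyroid tissue sections separates healthy or
benign nodules from carcinoma through a handful of molecular fingerprints:
carotenoid bands (1003, 1155, 1516 cm⁻¹) rise in papillary carcinoma (PTC)
and its follicular variant, oxidised cytochrome b and c bands (1376,
1638 cm⁻¹) dominate in healthy/benign tissue, and reduced cytochrome c
bands (747, 1125, 1302, 1584 cm⁻¹) mark follicular carcinoma. `ramanprom`
is for spectroscopists and computational researchers who want that analysis
as a tested, reproducible R pipeline rather than a one-off script:

1. **Band discovery.** Spectra are regridded to 1 cm⁻¹, normalised to unit
   sum, spline-smoothed; pooled local maxima are fitted with univariate
   unequal-variance Gaussian mixtures and the component count K chosen by
   BIC. Each component (μᵢ, σᵢ) yields the interval [μᵢ−σᵢ, μᵢ+σᵢ];
   contained intervals are removed and overlapping ones merged into a
   non-overlapping set of m intervals.
2. **Feature engineering.** Per spectrum and interval k, the prominence
   P_k is the maximum normalised intensity in the interval. All m(m−1)
   ordered ratios P_k/P_ℓ are formed (812 for m = 29) and for each pair
   the orientation with the larger mean/sd over the dataset is kept
   (406 for m = 29).
3. **Nested evaluation.** For each leave-one-out fold, a consensus of
   Boruta shadow-feature runs (states 1..S) selects the fold's features;
   the training rows are SMOTE-balanced (k = 10 neighbours) and a
   classifier (random forest, gradient-boosted trees, SVM, Gaussian naive
   Bayes) predicts the held-out instance. Replication over SMOTE seeds
   gives per-model AUC distributions; the best model is the median-AUC
   argmax (ties by IQR), its threshold maximises
   G = √(sensitivity·specificity).
4. **Explanation.** Per fold and run, Shapley values (in-package TreeSHAP
   for random forests, exact interventional enumeration otherwise)
   attribute the prediction to features; unselected features count as 0,
   values are averaged over runs and ranked by mean |SHAP|, with positive
   values driving toward the cancer label.

A synthetic spectrum generator with class-dependent band profiles makes the
whole pipeline runnable and testable without clinical data; see the methods
vignette (`vignettes/methods.Rmd`) for the model, parameter and design
discussion.

## Worked example

A desk-scale run on the well-separated synthetic preset (28 samples,
3 SMOTE seeds, 5 Boruta states, one candidate per model family):

```r
library(ramanprom)

cfg <- default_run_config(
  seed = 1,
  simulate = synthetic_config("well-separated", seed = 1,
                              n_per_class = c(healthy = 6, benign = 5,
                                              PTC = 10, FC = 3, `FV-PTC` = 4),
                              grid_range = c(400, 1800)),
  models = "reference", n_runs = 3, n_states = 5,
  boruta_max_iter = 60, boruta_num_trees = 60,
  boruta_include_tentative = TRUE, k_max = 30)
res <- run_pipeline(cfg)

res$evaluation$model_table
#>                                                                    model median_auc iqr_auc
#> 1                                  random-forest (ntree=50, max_depth=5)          1       0
#> 2 gradient-boosted-trees (num_parallel_tree=50, max_depth=5, nrounds=20)          1       0
#> 3                         support-vector-machine (cost=1, kernel=radial)          1       0
#> 4                                                   gaussian-naive-bayes          1       0

res$evaluation$aggregate$per_diagnosis
#>   diagnosis  n median_prob iqr_prob
#> 1    benign  5        0.02     0.08
#> 2        FC  3        0.74     0.13
#> 3    FV-PTC  4        1.00     0.01
#> 4   healthy  6        0.00     0.00
#> 5       PTC 10        1.00     0.00

head(res$ranking, 5)
#>   rank feature mean_abs_shap direction
#> 1    1 P12/P15        0.0153    cancer
#> 2    2   P8/P1        0.0145    cancer
#> 3    3 P13/P12        0.0138    cancer
#> 4    4  P8/P11        0.0134    cancer
#> 5    5  P13/P3        0.0133    cancer
```

Reading the output: 17 mixture components were selected by BIC and
finalised to 16 intervals; every model separates the classes perfectly
(median AUC 1), so the tie-break keeps the first grid candidate, the
reference random forest. Median predicted cancer probabilities order the
diagnoses as healthy ≈ benign < FC < FV-PTC ≈ PTC, and the top-ranked
features are ratios whose numerators sit in carotenoid-band intervals
(here P8 covers 1155 cm⁻¹ and P13 covers 1516 cm⁻¹), with higher values
driving the classifier toward the cancer label — the expected carotenoid
fingerprint.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/raman_pipeline.R --simulate well-separated --seed 7 --out out/
```

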