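---
title: "Methods: prominence-ratio classification of thyroid Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prominence-ratio classification of thyroid Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Raman spectra of thyroid tissue sections carry molecular fingerprints that
separate healthy or benign nodules from carcinoma: carotenoid bands
(1003, 1155, 1516 cm^-1) are elevated in papillary carcinoma (PTC) and its
follicular variant (FV-PTC), the oxidised cytochrome b and c bands
(1376, 1638 cm^-1) dominate in healthy/benign tissue, and reduced
cytochrome c bands (747, 1125, 1302, 1584 cm^-1) are strong in follicular
carcinoma (FC) and FV-PTC but nearly absent in PTC. `ramanprom` implements
a complete, reproducible analysis pipeline around these fingerprints:
unsupervised discovery of spectral intervals, prominence-ratio feature
engineering, imbalanced-data model evaluation, and Shapley-value
explanation. Because clinical spectra of this kind are not publicly
deposited, the package ships a synthetic generator that emulates the band
structure, so every stage is exercised end to end by code alone.

# Preprocessing and band discovery

Each spectrum (two columns: Raman shift in cm^-1, background-subtracted
intensity) is

1. linearly interpolated onto the integer grid (1 cm^-1 spacing), without
   extrapolation beyond the observed span;
2. normalised to unit sum, so intensities are comparable across samples;
3. smoothed with a cubic smoothing spline, then re-normalised (smoothing
   perturbs the sum at the order of the trace's roughness, and prominences
   are defined on unit-sum traces).

The spline penalty defaults to generalised cross-validation (`"gcv"`),
a parameter-free choice that adapts to the noise level; a fixed penalty can
be supplied instead, and a penalty of zero reproduces the input. The spline
uses every grid point as a knot: with the default reduced knot set
(about 200 knots for a 3500-point trace) the basis cannot represent sharp
bands and rings around them, which biases peak positions by several cm^-1 —
this was the single most consequential numerical choice in the module.

Local maxima are detected on each smoothed trace and filtered by
topographic prominence at a permissive default threshold of 0.5 % of the
trace's intensity range (`min_prominence_frac = 0.005`); smoothing, not the
threshold, is the main noise suppressor. Maxima pooled over all spectra are
fitted with univariate unequal-variance Gaussian mixtures (mclust, model
"V") for component counts K in 1..40, and K is selected by BIC. mclust's
agglomerative initialisation makes the fit deterministic, so no random
restarts are needed; the `seed` argument is retained for interface
stability. Each pooled maximum enters the fit as one unweighted
observation: the band structure is inferred from *where* maxima occur, not
how tall they are.

# Interval algebra

Every mixture component (mu, sigma) defines the closed interval
[mu - sigma, mu + sigma]. Intervals entirely contained in another are
removed (exact duplicates keep the copy with the smaller component index —
an arbitrary but deterministic tie rule the data never exercises), then
partially overlapping pairs are merged to [min lo, max hi] until no pair
intersects, and the survivors are reindexed 1..m by lower bound. Touching
endpoints count as overlap, so a shared grid point can never belong to two
intervals and prominence assignment is unambiguous. The union of intervals
is preserved exactly by both steps, and
|final| = |built| - #contained - #merge-events. An externally supplied
interval table can replace the mixture-derived one (`intervals_file`),
allowing published interval boundaries to be dropped in.

# Prominence-ratio features

The prominence P_k of a spectrum in interval k is its maximum unit-sum
intensity over the grid points of [lo_k, hi_k]; values below 1e-12 are
floored to 1e-12 (with a warning) so ratios stay finite on dead spectral
regions. All m(m-1) ordered ratios P_k/P_l are formed — 812 for m = 29 —
and for each unordered pair the orientation with the larger mean/sd
(sample standard deviation, n-1 denominator) across the *entire dataset*
is kept, giving m(m-1)/2 features (406 for m = 29). Computing the
selection statistic on the full dataset before any train/test split leaks
label-free distributional information into the folds; the pipeline
reproduces this design deliberately, because the selection is
label-independent and the alternative (per-fold selection) changes the
feature space across folds. With exactly two samples the statistic is
provably equal for both orientations (an algebraic identity), and the tie
rule (keep k < l) decides; this degenerate regime is documented rather
than forbidden. Ratios of a unit-sum spectrum make the features invariant
to rescaling the raw intensities of any single spectrum.

# Nested evaluation

The evaluation reproduces a two-loop design around a small, moderately
imbalanced dataset (25 negative vs 34 positive by default):

* **Per-fold Boruta consensus.** For each leave-one-out fold, the Boruta
  shadow-feature procedure runs once per random state (states 1..n_states)
  on the n-1 training rows, and the features confirmed by *every* state
  form the fold's consensus. Because the states are fixed and SMOTE plays
  no role in selection, the consensus depends only on the split and is
  computed once and reused across SMOTE seeds — an exact reorganisation
  that cuts the Boruta fits by the number of SMOTE seeds (100x at full
  scale). The in-package Boruta pairs every candidate with a permuted
  shadow copy, scores a hit when a ranger random forest (depth 5,
  impurity importance) ranks the feature above the best shadow, and
  decides features by a Bonferroni-corrected binomial test against
  p = 0.5, removing rejected features from later iterations. Consensus
  counts confirmed features only by default; `include_tentative = TRUE`
  widens it, which matters for small desk-scale runs where strict
  confirmation (which needs on the order of a dozen consecutive hits) is
  statistically out of reach for any single feature among many correlated
  ones. An empty strict consensus raises an error carrying per-feature
  confirmation counts; `fallback_frac` optionally substitutes a quorum
  rule.

* **SMOTE.** The minority class of each fold's training rows is
  oversampled to parity: each synthetic row is a + lambda (b - a) with
  lambda ~ U(0, 1), a a random minority row and b one of its k = 10
  nearest minority neighbours (k shrinks to size-1 with a warning when
  the minority is tiny). Each run's seed fully determines the draws.

* **Leave-one-out runs.** For SMOTE seeds 1..n_runs and each candidate
  model, every instance is held out once, the model is fitted on the
  balanced, consensus-restricted training rows, and the held-out
  positive-class probability recorded. Per run, AUC is the Mann-Whitney
  concordance of the n held-out probabilities, and the classification
  threshold maximises G = sqrt(sensitivity x specificity) over midpoints
  of consecutive distinct probabilities plus {0, 1}, with ties broken
  toward 0.5 and then downward.

* **Model selection.** Candidates are compared by median AUC over runs,
  ties by smaller IQR, remaining ties by grid order. The default grid
  varies random-forest trees {25, 50, 100} x depth {3, 5, 10},
  gradient-boosted parallel trees {25, 50, 100} x depth {3, 5, 10}, SVM
  cost {0.5, 1, 2, 3} x kernel {linear, polynomial, radial, sigmoid}, and
  Gaussian naive Bayes. Two portability notes: R's random forests split
  only by the Gini criterion (the entropy/log-loss variants of other
  ecosystems are not available, and were reported there as equivalent
  anyway), and depth is enforced via the maxnodes = 2^depth cap of
  randomForest. SVM probabilities come from e1071's built-in Platt
  scaling; AUC is invariant to that calibration, only the threshold
  location depends on it.

* **Aggregation.** Classifications at each run's own threshold are summed
  into a row-normalised 2x2 confusion matrix; per-instance stability is
  the fraction of runs agreeing with the instance's majority class,
  bucketed at 0 / 10 / 15 % discrepancy; per-diagnosis summaries take
  median and IQR over instances of the per-instance median probability.

* **Held-out protocol.** `classify_held_out()` trains on the full
  training table (one Boruta consensus, then per-seed SMOTE + fit) and
  scores new instances whose features were computed with the training
  intervals and feature orientations — the protocol used for spectra
  whose fingerprints contradict their histology.

# Explanation

Shapley values explain the positive-class probability, so positive
attributions push toward the cancer label by construction. Three routes
are implemented:

* an exact enumeration oracle over all feature subsets with the factorial
  weights (up to 12 features), used for verification;
* path-dependent TreeSHAP for randomForest forests, written in-package:
  per tree it computes, in polynomial time, the exact Shapley values of
  the cover-conditional expectation value function, where node covers are
  taken from the tree's in-bag training counts (the data each tree was
  grown on). The tests verify equality with the enumeration oracle and
  local accuracy (attributions + base value = the forest's vote
  fraction);
* for non-tree families, an exact interventional explainer that
  marginalises over a background set (the fold's SMOTE-augmented training
  table, subsampled deterministically to 25 rows) when the fold has at
  most 12 features, with seeded permutation sampling beyond that.
  Gradient-boosted models use xgboost's native TreeSHAP, whose
  attributions live on the log-odds margin scale.

Per fold and SMOTE run, the held-out instance is attributed over the
fold's consensus features; features outside the consensus receive 0 for
that run; the per-feature mean over runs forms the explanation matrix.
Features are ranked by mean |SHAP| across instances, and each carries a
direction — the sign of the correlation between feature value and SHAP
value — read as "higher values drive toward cancer" (or healthy/benign).

# The synthetic generator

`synthetic_config()` defaults encode the study conditions the pipeline is
designed for: 59 samples (14 healthy, 11 benign, 25 PTC, 4 FC, 5 FV-PTC),
spectra on 100-3600 cm^-1 at 1 cm^-1 sampling (offset from the integers
so regridding is exercised). Each spectrum is a sum of Gaussian bands —
the nine diagnostic bands plus nine class-neutral nuisance bands at
common tissue positions (620, 856, 936, 1066, 1220, 1445, 1660, 2850,
2930 cm^-1) — with log-normal amplitudes whose class profiles encode the
fingerprints above, plus N(0, 1.5) band-centre jitter, a small random
quadratic residual baseline (the spectra emulate already
background-subtracted data), and additive Gaussian noise. Band widths
(sigma 5-11 cm^-1) are typical of condensed-phase tissue bands at this
resolution and chosen so that the closest band pair (1638/1660) remains
resolvable; the noise standard deviation (0.005 of the amplitude unit,
i.e. a fraction of a percent of the strongest band) matches
scan-accumulated, instrument-smoothed traces and keeps detected maxima
dominated by real bands, mirroring the clean pooled-maximum structure the
real study reports. The `well-separated` preset shrinks amplitude
dispersion (sdlog 0.25 vs 0.45) and noise and multiplies the class
contrast by 1.5; it is the preset under which ground-truth recovery
(best-model AUC, carotenoid-feature selection, SHAP directions) is
expected to be essentially deterministic.

What the generator does *not* emulate: non-Gaussian line shapes,
correlated (pink) instrument noise, fluorescence residuals, cosmic-ray
artifacts, within-patient correlation between measurement points, and any
real biochemical covariance between bands beyond the class-level
amplitude profiles. Passing tests therefore demonstrate that the
*pipeline* recovers structure it is designed to detect, not that the
classifier's clinical performance would replicate.

Ambiguous-sample modes override one fingerprint while retaining the
nominal label: `cancer-no-carotenoid` (PTC amplitudes with the healthy
carotenoid profile), `benign-weak-oxcytb` (benign with the 1376 cm^-1
band attenuated twenty-fold), and `benign-with-carotenoid` (benign with
the PTC carotenoid profile, the mutation-carrying case).

# Problem sizes and determinism

Full-scale settings (100 SMOTE seeds, 100 Boruta states, max_iter 500,
the complete model grid) are faithful to the study design but
computationally heavy; the package's desk-scale runs use 5 SMOTE seeds,
10 Boruta states, max_iter 100 and one candidate per model family
(`reference_model_grid()`), sizes at which the well-separated preset is
recovered in a few minutes on one core. All randomness flows from
explicit seeds (master seed -> per-spectrum seeds; Boruta states 1..S;
SMOTE seeds 1..R; per-fit model seeds derived from run and fold), every
seed is echoed into the provenance record, and an identical configuration
reproduces a byte-identical results document.

# Known limitations

* Strict all-states Boruta consensus is statistically demanding at small
  n; desk-scale configurations should use `include_tentative` or a
  fallback quorum, as the smoke tests do.
* The discovered interval set occasionally contains one broad interval
  spanning several true bands when a wide mixture component survives
  BIC; prominences then reflect the tallest band in the span.
* TreeSHAP is implemented for randomForest classification forests only;
  other tree ensembles go through xgboost's native explainer or the
  interventional route.
* The reciprocal-selection statistic is computed once on the full
  dataset (by design, see above); set `selection` aside if strict
  fold-purity is required for a methodological comparison.
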