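---
title: "Estimating leaf dry matter from full-range reflectance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf dry matter from full-range reflectance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(specstack)
```

## The problem

Leaf dry matter content — DM, the percent of fresh mass remaining after oven
drying, `DM = 100 * m_dry / m_fresh` — is a structural trait driven by
cellulose, hemicellulose and lignin. These constituents absorb in broad,
overlapping complexes across the shortwave infrared (SWIR, roughly
1300–2500 nm), entangled with the much stronger water absorption features
near 1450 and 1940 nm. DM is therefore a *spectrally diffuse* trait: no
single wavelength pair isolates it, which is why narrow-band indices that
work well for water status tend to fail for DM on heterogeneous material.

`specstack` treats DM estimation from full-range (350–2500 nm, 1 nm grid,
2151 bands) leaf reflectance as a regression problem and implements the
whole modeling ladder:

1. **index baselines** — single spectral indices as lone predictors, then an
   elastic net over the standardized index table;
2. **full-spectrum base learners** — PCR, PLSR, elastic net, random forest,
   gradient-boosted trees and Gaussian process regression, trained on
   PCA-reduced standardized spectra (PLSR on standardized spectra directly)
   and tuned by repeated k-fold cross-validation;
3. **candidate-level stacking** — the top configurations of every family are
   blended by a non-negative LASSO meta-learner fitted on out-of-fold
   predictions;
4. **diagnostics** — contiguous 10 nm band permutation importance on the
   test set, and residual-versus-predicted analysis with a local smoother.

## The synthetic generator

No public leaf dataset accompanies the methodology this package implements,
so `generate_dataset()` provides a mechanism with *known* ground truth. It is
an analytic stand-in, not a radiative-transfer model; its contract is to
reproduce (a) a realistic right-skewed DM distribution and (b) SWIR-localized
DM information, so that every downstream stage can be validated end to end.

**Trait law.** DM is drawn from a shifted gamma,
`DM = shift + Gamma(shape, scale)`, with defaults solved by method of moments
from a target mean of 16.11 %, standard deviation 6.55 % and skewness 1.45 —
the kind of pooled multi-crop distribution a leaf-clip campaign across
species and treatments produces. `2/sqrt(shape) = skew` gives
`shape ≈ 1.90`, `scale = sd/sqrt(shape) ≈ 4.75`, `shift ≈ 7.08`.

**Spectrum mechanism.** Each spectrum starts from an analytic template
(`leaf_template()`): a low visible trough with a green bump at 550 nm, a
logistic red edge near 715 nm rising to a NIR plateau around 0.48, and a
gentle SWIR decline. Absorption features are subtracted as compactly
supported Gaussian dips (truncated and edge-rescaled at a 50 nm support
radius):

* water features at 1450 and 1940 nm with depth proportional to the water
  fraction, which follows the negative link
  `water = 1.0 - 0.01 * DM + noise` — drier leaves hold less water;
* dry-matter features at 1720, 2100 and 2300 nm with depth proportional to
  DM.

The compact support keeps the DM signal strictly local in wavelength, which
is what makes the band-importance localization checks sharp: a band more
than 50 nm from every feature center carries *exactly* zero DM information
in the noise-free limit.

**Noise.** Four terms, all configurable: (i) *driver noise* — independent
Gaussian perturbations of the DM value entering each dry-matter depth law,
in DM % units. This is the information ceiling: with 3 features and
per-feature noise sd `tau`, the best linear read-out of DM from the depths
achieves `R^2 = var(DM) / (var(DM) + tau^2/3)`. The default is calibrated by
`driver_noise_for_r2(0.9)` so the ceiling sits at R² ≈ 0.9, matching the
accuracy regime the method targets on real leaves. (ii) low-order polynomial
baseline wiggle (sd 0.004), (iii) per-sample multiplicative scatter
(sd 0.01), (iv) additive white noise per band (sd 0.002) — mild
instrument-like perturbations for laboratory-quality spectra.
`mode = "nonlinear"` adds a quadratic interaction of the 1720/2100 nm depths
at 1550 nm; `mode = "null"` permutes the DM labels after generation,
severing the trait–spectrum link.

**What the generator does not emulate:** real spectra have full-rank,
spatially correlated noise, species-specific template shapes, broad
(100 nm+) absorption wings, and instrument artifacts such as detector-joint
steps. Passing tests on synthetic data therefore demonstrate correctness of
the *machinery* (no leakage, correct CV bookkeeping, correct solver, correct
localization), not field-level accuracy on any particular crop.

## Preprocessing

* **Artifact screen** (`screen_artifacts()`): flags reflectance outside
  [0, 1], absolute first differences above 0.2, and non-finite cells —
  the screen that removes grossly implausible captures before modeling.
* **Savitzky–Golay smoothing** is available (quadratic, windows 7–13,
  mirror-padded edges so the 2151-band grid keeps its length) but **off by
  default**: on laboratory-quality spectra smoothing tends to blunt the
  subtle SWIR structure the models rely on, and it did not help
  cross-validated accuracy in this workflow's reference setting.
* **Standardization** uses per-band train-only means and sds (denominator
  n−1). Zero-variance bands — possible in synthetic data — are dropped with
  a warning, with wavelength bookkeeping preserved for importance reporting.
* **PCA** on the standardized training spectra retains the smallest number
  of components reaching 99 % cumulative explained variance (`k_max`);
  learners treat their component count as a hyperparameter bounded by
  `k_max`. Loading signs are fixed (largest-magnitude element positive) so
  score signs are reproducible across platforms.
* **Leakage policy**: by default the standardizer and PCA are refit inside
  every CV training fold (`prep_opts(pca_refit = "fold")`). Refitting once
  on the full training set is available (`"train"`) but the per-fold variant
  is the conservative reading whenever the resampling is supposed to
  estimate out-of-sample error.

## The index library

`spectral_indices()` ships 24 definitions: normalized differences (NDII,
NDWI variants, NDVI, NWI, NDMI, DMCI, …), pure ratios (WI, SRWI, LWI, MSI,
DWSI-1..4), the log-ratio lignin index NDLI (base 10; the value is invariant
to the base since it cancels in the ratio), the linear-combination cellulose
index CAI = R2000 − 0.5·(R2100 + R1900), and composite SWSI/DWSI-5 forms.
Several published index collections count 26 entries for this task; only
these 24 have unambiguous printed formulas, and the registry is extensible.
Useful identities (all tested): on a flat spectrum every normalized
difference is 0 and every pure ratio is 1; normalized differences and ratios
are invariant to multiplying the whole spectrum by a constant, while CAI
scales linearly.

## Tuning and selection

* **Search spaces** (`hyperparam_space()`): component-only families (PCR,
  PLSR) use evenly spaced integer grids; multi-parameter families use a
  seeded Latin-hypercube sample within the documented bounds, log-scaled for
  penalties, learning rates and the GPR bandwidth. Row/column subsampling
  for boosted trees defaults to [0.5, 1.0]. GPR uses a two-stage search:
  components swept at the log-midpoint bandwidth, then the bandwidth swept
  at the stage-1 winner.
* **GPR** is the exact RBF-kernel posterior mean,
  `k(x, x') = exp(-sigma * ||x − x'||^2)` on internally standardized scores,
  with a fixed diagonal jitter of 1e-6 for numerical stability.
* **Cross-validation**: repeated k-fold (default 10 × 3) with one shared
  fold assignment across *all* families and configurations — this is what
  licenses stacking on the out-of-fold predictions. Per configuration, the
  CV RMSE mean and its resample standard error (sd over the folds × repeats
  held-out RMSEs divided by √(folds·repeats)) are retained along with the
  full out-of-fold prediction matrix.
* **One-SE rule** (`select_one_se()`): among configurations within one
  standard error of the minimum mean RMSE, pick the simplest. "Simplest" is
  ordered: fewer components, then shallower trees, then fewer trees, then
  larger terminal nodes, then smaller mtry, then larger penalty; remaining
  ties break on lower mean RMSE and finally a deterministic configuration
  hash. Whether one-SE selection should gate stacking as well as the
  single-model report is genuinely open; here it is applied for the
  single-model benchmark, while the stack receives the top-m candidates per
  family ranked by mean CV RMSE.

## Stacking

The meta-learner solves

$$\min_{w \ge 0,\, b} \frac{1}{2n} \sum_i \Big(y_i - b - \sum_c w_c\,o_{ic}\Big)^2 + \lambda \sum_c w_c$$

on the out-of-fold matrix (repeats averaged per sample — averaging reduces
meta-design noise), with a near-vanishing fixed penalty λ = 1e-6 and an
unpenalized intercept. No sum-to-one constraint is imposed; non-negativity
alone already yields sparse, interpretable weights, and nothing forces the
retained weights to sum to 1.

**Skill screen.** Before blending, candidates whose cross-validated R² falls
below 0.1 (CV RMSE above √0.9 times the trait's standard deviation) are
excluded from the library unless none would remain. Such candidates sit
within sampling noise of the trivial mean predictor: their out-of-fold
columns are nearly constant, so they can only enter the meta-fit through
degeneracy with the intercept — and a member selected that way (for example
an over-narrow RBF kernel that predicts the fold mean out of fold but
*interpolates* the training data once refit) behaves entirely differently
after the full-train refit, corrupting the ensemble's training fit while
contributing nothing to prediction. The screen is deterministic, uses
training information only, and can be disabled
(`build_candidate_library(skill_screen = FALSE)`).

**Solver.** A cyclic coordinate-descent phase (non-negativity by clipping,
deterministic coordinate order) followed by an exact active-set refinement:
penalized least squares solved on the current active set, coordinates with
negative solutions dropped, and the Karush–Kuhn–Tucker conditions of the
full problem verified before convergence is declared. The refinement exists
because strong candidates produce *nearly collinear* out-of-fold columns
(correlations above 0.999 are routine), along whose flat valley plain
coordinate descent crawls indefinitely. Exactly duplicated columns make the
active-set system singular; in that case the coordinate-descent solution is
kept, so ties resolve deterministically by coordinate order. Members with
positive weight are refit on the full training set; prediction is
`b + sum(w_c * member_c(x))`.

## Diagnostics

* **Band permutation importance**: the grid is tiled into contiguous 10 nm
  bands (the 1-band remainder at 2500 nm is kept and flagged as short). For
  each band and repeat, one shared row permutation is applied jointly to all
  wavelengths in the band — permuting wavelengths independently would break
  within-band correlation and overstate importance — and the increase in
  test RMSE is recorded. Permutation is applied to *raw* reflectance before
  standardization and PCA, so importance propagates through the entire
  pipeline exactly as a corrupted measurement would.
* **Residual diagnostics**: residuals against predictions with a
  tri-cube-weighted local linear smoother (default span 0.75) evaluated on a
  uniform grid over the prediction range. Local *linear* fits carry a small
  curvature bias on strongly curved trends; the smoother is a trend display,
  not an estimator.

## Numerical conventions

* R² is always `1 − SS_res/SS_tot` (it can be negative); RMSE is in DM
  percentage points.
* Skewness and kurtosis use the adjusted (bias-corrected) estimators;
  standard deviations use n−1 throughout.
* Reflectance is clipped to (0.001, 1) at generation so log- and ratio-type
  indices never divide by zero; zero index denominators in real data yield
  `NA` with a warning and exclude the sample from that index's regression
  only.
* Every random step (trait sampling, splitting, fold assignment,
  Latin-hypercube draws, permutations) consumes an explicit seed and
  restores the caller's RNG state, so a configuration reproduces
  bit-identical results.
* Learner configurations that fail to fit (e.g. component counts beyond the
  data's effective rank, where the PLS projection degenerates) are recorded
  as failed and excluded with a warning; they never abort a run.

## Problem sizes in the test suite

The packaged checks run the full machinery at deliberately modest sizes —
typically n = 120–500 samples, 3–5 folds × 1 repeat, 4–8 configurations per
family, and the linear-algebra families (PLSR, PCR, GPR) for the multi-seed
recovery studies. These sizes are large enough for the statistical
properties being asserted (signal recovery at the calibrated R² ≈ 0.9
ceiling, stack-versus-best-single comparisons, importance localization,
null-mode controls) while keeping the whole suite inexpensive to run; the
reference setting of 10 folds × 3 repeats with top-20 candidate libraries
remains the package default for real analyses.

## Known limitations

* The learner zoo ships six families (PCR, PLSR, elastic net, random
  forest, XGBoost, GPR); gradient boosting is represented by XGBoost alone,
  with no separate leaf-wise (LightGBM-style) boosting family.
* The synthetic mechanism is low-rank by construction; effective spectral
  rank (and hence `k_max` and feasible PLSR component counts) is far below
  what 2151-band field data support.
* GPR is exact and therefore O(n³) in training samples; it is intended for
  the few-hundred-sample regime this workflow targets.
* The stack's uncertainty is not quantified; weights describe composition,
  not credibility intervals.
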