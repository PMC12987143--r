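# specstack

Stacked ensemble estimation of leaf dry matter content from full-range
hyperspectral reflectance.

## The problem

Leaf dry matter content (DM, the percent of fresh mass remaining after oven
drying, `DM = 100 * m_dry / m_fresh`) is a key structural trait for crop
monitoring and precision agriculture, but it is *spectrally diffuse*:
cellulose, hemicellulose and lignin absorb in broad, overlapping complexes
across the shortwave infrared (SWIR), entangled with the dominant water
features near 1450 and 1940 nm. Narrow-band spectral indices that work well
for leaf water status capture only a fraction of DM variation on
heterogeneous, multi-species material. `specstack` is for plant-phenomics
and chemometrics practitioners who want to go beyond single indices: it
implements the full modeling ladder from index baselines to a stacked
ensemble of complementary full-spectrum learners, plus the diagnostics to
interpret it.

## The method

Given spectra `R(lambda)` on the 350–2500 nm grid (1 nm, 2151 bands) with
measured DM:

1. **Baselines.** Every index in a 24-entry registry (NDVI, NDII, NDWI
   variants, WI, NDLI, CAI, NDMI, DMCI, SWSI/DWSI families, ...) as a lone
   OLS predictor, then an elastic net over the standardized index table.
2. **Base learners.** Spectra are standardized per band (train-only
   statistics) and reduced by PCA to the smallest K capturing 99% of
   variance. Six families — PCR, PLSR, elastic net, random forest, XGBoost
   and Gaussian process regression — are tuned over documented search spaces
   by repeated k-fold cross-validation (default 10 folds x 3 repeats, one
   shared fold assignment for all candidates), with one-standard-error
   selection for the single-model report.
3. **Stacking.** The top-m configurations per family form a candidate
   library; their out-of-fold predictions `o_ic` become the design matrix of
   a non-negative LASSO meta-learner

   minimize over w >= 0, b:  (1/2n) * sum_i (y_i - b - sum_c w_c o_ic)^2 + lambda * sum_c w_c

   with fixed `lambda = 1e-6`. Members with positive weight are refit on the
   full training set; the ensemble predicts `b + sum_c w_c * f_c(x)`.
4. **Diagnostics.** Permutation importance of contiguous 10 nm bands
   (raw-reflectance permutation propagated through the whole pipeline) and
   residual-versus-predicted plots with a local smoother.

Because the reference data for this methodology are not public, the package
ships a seeded synthetic leaf-spectra generator with a known DM -> spectrum
mechanism (right-skewed trait law, DM-linked water fraction, SWIR absorption
features, instrument-like noise) so that every stage is testable against
ground truth. See the vignette `vignettes/dry-matter-stacking.Rmd` for the
model details and design decisions.

## Worked example

```r
library(specstack)

sim <- generate_dataset(synth_config(n = 481, seed = 1))
sp  <- split_dataset(sim$dataset, train_frac = 0.8, seed = 2025)
cohort_stats(sp$train$dm, sp$test$dm)
head(index_benchmark(sp$train, sp$test), 4)

tn <- tune_learners(sp$train, families = c("plsr", "pcr", "gpr"),
                    budgets = c(plsr = 8, pcr = 6, gpr = 6),
                    cv = cv_spec(folds = 5, repeats = 1, seed = 1))
single_model_benchmark(tn, sp$train, sp$test)

st <- dm_stack(sp$train, tuning = tn, top_m = 5)
summary(st)
evaluate_learner(st, sp$test)
band_permutation_importance(st, sp$test, repeats = 3, seed = 1)
```

This prints (abridged):

```
Descriptive statistics (%):
        n   mean median    sd   min    max  skew  kurt
train 384 15.852 14.183 6.334 7.516 52.400 1.506 4.208
test   97 15.731 14.210 6.370 7.638 37.114 1.109 1.026

Two-group tests:
               test  statistic   p_value
3   fligner_killeen 2.0071e-01 6.541e-01
4 wilcoxon_rank_sum 1.9035e+04 7.372e-01

-- index benchmark (top 4) --
 index     rmse        r2
   LWI 2.549590 0.8381159
  DMCI 2.789620 0.8062001
  NDMI 3.219485 0.7418713
   CAI 3.577980 0.6811846

-- single models (one-SE selection per family) --
 family     id num_comp  cv_rmse test_rmse   test_r2
    pcr  pcr_1       10 1.220412  1.245091 0.9613930
   plsr plsr_5       19 1.363449  1.327980 0.9560816
    gpr  gpr_1       10 1.708473  1.362010 0.9538019

<dm_stack> 3 members from 13 candidates (top 5 per family)
  meta-learner: non-negative LASSO, lambda = 1e-06, intercept = -0.083
  training fit: RMSE 1.158%, R2 0.967

Retained base learners (3 members, intercept -0.083):
 Family Model      Weight  K sigma Trees Depth LR mtry min_n
    PCR pcr_1 0.791838255 10    NA    NA    NA NA   NA    NA
    PCR pcr_2 0.207660556 38    NA    NA    NA NA   NA    NA
    GPR gpr_2 0.005896389 10   0.1    NA    NA NA   NA    NA

stack test: RMSE 1.249%, R2 0.961

Band permutation importance: 216 bands, baseline RMSE 1.249%
Top bands by mean delta RMSE:
 start  end center delta_rmse_mean delta_rmse_sd short
  1950 1959 1954.5          0.0669        0.0199 FALSE
  1920 1929 1924.5          0.0648        0.0198 FALSE
  1440 1449 1444.5          0.0593        0.0152 FALSE
  1450 1459 1454.5          0.0584        0.0160 FALSE
  1960 1969 1964.5          0.0486        0.0148 FALSE
```

Reading the output: the train/test subsets are statistically comparable
(variance-homogeneity and rank-sum p-values well above 0.05); the best
single index explains ~84% of test variance while the stacked ensemble
reaches R² = 0.961 (RMSE 1.25 percentage points of DM); the meta-learner
keeps 3 of 13 candidates with non-negative weights summing to ~1.0; and
permutation importance localizes the prediction-relevant wavelengths at the
generator's water features (1440–1460, 1920–1960 nm), exactly where this
synthetic dataset carries its DM information.

The one-command version of the same workflow is
`run_pipeline(pipeline_config(simulate = synth_config(n = 481, seed = 1)), "runs/demo")`,
which writes train/test CSVs, the cohort report, the index benchmark, the
single-model table, stack weights, band importances, residuals and
`metrics.json` to the run directory.

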