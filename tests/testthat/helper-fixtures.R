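# Shared fixtures: all synthetic, generated at test time.

# Small default-mechanism dataset.
quick_ds <- function(n = 60, seed = 1, ...) {
  generate_dataset(synth_config(n = n, seed = seed, ...))$dataset
}

# Noise-free configuration: spectra are an exact linear function of DM.
# The 1940 nm water feature is shallower than the default so its core never
# saturates at the 0.001 reflectance floor (saturation would bend the
# otherwise linear DM -> spectrum map).
noisefree_config <- function(n = 60, seed = 1, ...) {
  feats <- specstack:::default_features()
  feats$depth_coef[feats$center == 1940] <- 0.25
  synth_config(n = n, seed = seed, features = feats,
               driver_noise_sd = 0, water_noise_sd = 0,
               baseline_wiggle_sd = 0, mult_noise_sd = 0, add_noise_sd = 0, ...)
}

# Dataset crafted band-by-band: template backbone with selected wavelength
# columns overridden (each override a function of dm or a constant).
craft_ds <- function(dm, overrides = list(), seed = NULL) {
  wl <- default_grid()
  n <- length(dm)
  refl <- matrix(rep(leaf_template(wl), each = n), n, length(wl))
  for (nm in names(overrides)) {
    j <- which(wl == as.integer(nm))
    v <- overrides[[nm]]
    refl[, j] <- if (is.function(v)) v(dm) else v
  }
  spectra_dataset(refl, dm, wavelengths = wl)
}

# Random positive "flat" spectra: every band equal within a sample.
flat_spectra <- function(n, seed = 1) {
  levels <- specstack:::with_seed(seed, stats::runif(n, 0.05, 0.95))
  refl <- matrix(rep(levels, times = length(default_grid())), n)
  spectra_dataset(refl, dm = rep(10, n), wavelengths = default_grid())
}

# Non-negative least squares with unpenalized intercept: alternating
# pracma::lsqnonneg / intercept update. Independent oracle for the
# coordinate-descent meta-learner.
nnls_intercept_oracle <- function(O, y, max_iter = 500, tol = 1e-12) {
  b <- mean(y)
  w <- rep(0, ncol(O))
  for (i in seq_len(max_iter)) {
    w_new <- pracma::lsqnonneg(O, y - b)$x
    b_new <- mean(y - O %*% w_new)
    if (max(abs(w_new - w)) < tol && abs(b_new - b) < tol) {
      w <- w_new; b <- b_new; break
    }
    w <- w_new; b <- b_new
  }
  list(weights = w, intercept = b)
}
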