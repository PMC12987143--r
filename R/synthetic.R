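# Synthetic leaf reflectance generator: a known DM -> spectrum mechanism so
# every downstream stage (indices, tuning, stacking, importance) can be tested
# against ground truth.

#' Shifted-gamma trait law from target moments
#'
#' Method-of-moments solve for a shifted gamma distribution
#' `DM = shift + Gamma(shape, scale)` matching a target mean, standard
#' deviation and skewness: `2/sqrt(shape) = skew`, `scale = sd*sqrt(shape)...`
#' more precisely `scale = sd / sqrt(shape)`, `shift = mean - shape*scale`.
#'
#' @param mean,sd,skew Target moments; `sd > 0`, `skew > 0`.
#' @return List with `shape`, `scale`, `shift`.
#' @export
trait_law_from_moments <- function(mean = 16.11, sd = 6.55, skew = 1.45) {
  if (sd <= 0 || skew <= 0) stopf("need sd > 0 and skew > 0")
  shape <- (2 / skew)^2
  scale <- sd / sqrt(shape)
  shift <- mean - shape * scale
  if (mean <= 0) stopf("trait law implies non-positive mean")
  list(shape = shape, scale = scale, shift = shift)
}

default_features <- function() {
  data.frame(
    center = c(1450, 1940, 1720, 2100, 2300),
    width  = c(18, 22, 15, 18, 15),
    driver = c("water", "water", "dm", "dm", "dm"),
    depth_coef = c(0.32, 0.42, 0.0045, 0.0060, 0.0040),
    stringsAsFactors = FALSE
  )
}

#' Noise level matching a target depth-oracle R^2
#'
#' The generator perturbs each dry-matter feature depth with independent
#' Gaussian noise in DM units. With `p` dry-matter features of per-feature
#' noise sd `tau`, the best linear read-out of DM from the depths achieves
#' `R^2 = var(DM) / (var(DM) + tau^2/p)`; this inverts that relation.
#'
#' @param r2 Target oracle R^2 in (0, 1).
#' @param sd_dm Standard deviation of the trait law (DM %).
#' @param n_features Number of dry-matter features carrying the signal.
#' @return Per-feature driver noise sd (DM %).
#' @export
driver_noise_for_r2 <- function(r2 = 0.9, sd_dm = 6.55, n_features = 3) {
  if (r2 <= 0 || r2 >= 1) stopf("`r2` must lie in (0, 1)")
  sqrt(n_features * sd_dm^2 * (1 - r2) / r2)
}

#' Synthetic generator configuration
#'
#' Defines the study conditions emulated by the generator: a right-skewed
#' shifted-gamma dry matter law, a negative DM-water link, SWIR absorption
#' features driven by water fraction and DM, and instrument-like noise.
#'
#' @param n Number of samples.
#' @param seed Integer seed; the full dataset is reproducible from
#'   `(config, seed)`.
#' @param trait_law List `shape`/`scale`/`shift`; default matches a mean of
#'   16.11%, sd 6.55% and skewness 1.45 via [trait_law_from_moments()].
#' @param water_intercept,water_slope Water fraction model
#'   `water = intercept + slope * dm + noise` (slope negative: drier leaves
#'   hold less water).
#' @param water_noise_sd Gaussian sd of the water fraction noise.
#' @param features Data frame with columns `center` (nm), `width` (nm),
#'   `driver` (`"water"` or `"dm"`), `depth_coef` (absorption depth per unit
#'   driver). Defaults to water features at 1450/1940 nm and dry-matter
#'   features at 1720/2100/2300 nm.
#' @param driver_noise_sd Sd of the per-feature noise added to DM before the
#'   depth law is applied (DM %); controls the information ceiling. Default
#'   calibrated for a depth-oracle R^2 of 0.9.
#' @param baseline_wiggle_sd Sd of random low-order polynomial baseline
#'   coefficients (reflectance units).
#' @param mult_noise_sd Sd of the per-sample multiplicative scatter factor.
#' @param add_noise_sd Sd of additive white noise per band.
#' @param mode `"linear"` (DM enters spectra linearly), `"nonlinear"` (adds a
#'   quadratic interaction of two feature depths), or `"null"` (DM labels
#'   permuted: no DM-spectrum link).
#' @param nl_coef,nl_center,nl_width Nonlinear-mode interaction feature:
#'   depth = `nl_coef` x (depth at 1720 nm) x (depth at 2100 nm).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n = 481, seed = 1,
                         trait_law = trait_law_from_moments(),
                         water_intercept = 1.0, water_slope = -0.01,
                         water_noise_sd = 0.015,
                         features = default_features(),
                         driver_noise_sd = driver_noise_for_r2(0.9),
                         baseline_wiggle_sd = 0.004,
                         mult_noise_sd = 0.01,
                         add_noise_sd = 0.002,
                         mode = c("linear", "nonlinear", "null"),
                         nl_coef = 10, nl_center = 1550, nl_width = 40) {
  mode <- match.arg(mode)
  if (n < 1L) stopf("`n` must be >= 1")
  stopifnot(is.data.frame(features),
            all(c("center", "width", "driver", "depth_coef") %in% names(features)))
  if (any(features$width <= 0)) stopf("feature widths must be > 0")
  if (any(features$depth_coef < 0)) stopf("feature depths must be >= 0")
  if (any(c(water_noise_sd, driver_noise_sd, baseline_wiggle_sd,
            mult_noise_sd, add_noise_sd) < 0)) stopf("noise sds must be >= 0")
  if (!all(features$driver %in% c("water", "dm"))) {
    stopf("feature drivers must be 'water' or 'dm'")
  }
  mean_dm <- trait_law$shift + trait_law$shape * trait_law$scale
  if (!is.finite(mean_dm) || mean_dm <= 0) stopf("trait law implies mean <= 0")
  structure(list(
    n = as.integer(n), seed = seed, trait_law = trait_law,
    water_intercept = water_intercept, water_slope = water_slope,
    water_noise_sd = water_noise_sd, features = features,
    driver_noise_sd = driver_noise_sd,
    baseline_wiggle_sd = baseline_wiggle_sd,
    mult_noise_sd = mult_noise_sd, add_noise_sd = add_noise_sd,
    mode = mode, nl_coef = nl_coef, nl_center = nl_center, nl_width = nl_width
  ), class = "synth_config")
}

#' Sample dry matter values from the trait law
#'
#' @param n Number of draws.
#' @param trait_law Shifted-gamma parameters (see [trait_law_from_moments()]).
#' @param seed Integer seed.
#' @return Numeric DM vector (%), clipped to (0, 100).
#' @export
sample_traits <- function(n, trait_law = trait_law_from_moments(), seed = 1) {
  mean_dm <- trait_law$shift + trait_law$shape * trait_law$scale
  if (!is.finite(mean_dm) || mean_dm <= 0) stopf("trait law implies mean <= 0")
  dm <- with_seed(seed, trait_law$shift +
                    stats::rgamma(n, shape = trait_law$shape, scale = trait_law$scale))
  pmin(pmax(dm, 1e-3), 100 - 1e-3)
}

#' Analytic leaf reflectance template
#'
#' The featureless backbone: a low visible trough with a green bump at 550 nm,
#' a logistic red edge near 715 nm rising to a near-infrared plateau around
#' 0.48, and a gentle decline through the shortwave infrared. Absorption
#' features are subtracted from this template by [render_spectrum()].
#'
#' @param wavelengths Wavelengths (nm); default [default_grid()].
#' @return Reflectance vector.
#' @export
leaf_template <- function(wavelengths = default_grid()) {
  wl <- as.numeric(wavelengths)
  0.04 +
    0.045 * exp(-(wl - 550)^2 / (2 * 35^2)) +
    0.44 * stats::plogis((wl - 715) / 18) -
    0.16 * stats::plogis((wl - 1500) / 250)
}

# Compactly supported absorption feature: a Gaussian bell truncated at
# `support` nm from the center, edge-subtracted and rescaled so the shape is
# continuous, equals 1 at the center and is exactly zero beyond the support
# radius. Compact support keeps the DM signal strictly local in wavelength.
gaussian_dip <- function(wl, center, width, support = 50) {
  edge <- exp(-support^2 / (2 * width^2))
  pmax(0, (exp(-(wl - center)^2 / (2 * width^2)) - edge) / (1 - edge))
}

#' Render a noise-free leaf spectrum for a given dry matter value
#'
#' Subtracts Gaussian absorption features from the analytic template: water
#' features with depth proportional to the water fraction and dry-matter
#' features with depth proportional to DM. With all noise terms at zero this
#' is the exact noiseless mechanism used by [generate_dataset()].
#'
#' @param dm Dry matter content (%), strictly between 0 and 100.
#' @param config A [synth_config()].
#' @param water Water fraction; defaults to the config's noiseless link
#'   `water_intercept + water_slope * dm`.
#' @param depths Optional explicit per-feature depths (overrides the depth
#'   laws; used for replaying stored latents).
#' @return Reflectance vector on the 350-2500 nm grid, clipped to
#'   (0.001, 1).
#' @export
render_spectrum <- function(dm, config = synth_config(), water = NULL, depths = NULL) {
  if (any(dm <= 0 | dm >= 100)) stopf("`dm` must lie strictly between 0 and 100")
  wl <- default_grid()
  feats <- config$features
  if (is.null(water)) water <- config$water_intercept + config$water_slope * dm
  if (is.null(depths)) {
    depths <- ifelse(feats$driver == "water",
                     feats$depth_coef * water,
                     feats$depth_coef * dm)
  }
  spec <- leaf_template(wl)
  for (j in seq_len(nrow(feats))) {
    spec <- spec - depths[j] * gaussian_dip(wl, feats$center[j], feats$width[j])
  }
  if (config$mode == "nonlinear") {
    i1 <- which(feats$center == 1720)[1]
    i2 <- which(feats$center == 2100)[1]
    if (!is.na(i1) && !is.na(i2)) {
      spec <- spec - config$nl_coef * depths[i1] * depths[i2] *
        gaussian_dip(wl, config$nl_center, config$nl_width)
    }
  }
  pmin(pmax(spec, 0.001), 1)
}

#' Generate a synthetic leaf spectra dataset
#'
#' Draws dry matter values from the trait law, derives a water fraction via
#' the (noisy) negative DM-water link, perturbs dry-matter feature depths with
#' driver noise, renders each spectrum from the analytic template, and adds
#' polynomial baseline wiggle, multiplicative scatter and additive white
#' noise. In `mode = "null"` the DM labels are finally permuted, severing the
#' DM-spectrum link.
#'
#' @param config A [synth_config()].
#' @return List with `dataset` (a [spectra_dataset()]) and `record` (data
#'   frame of per-sample latents: dm, water, feature depths, scatter factor,
#'   baseline coefficients).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n
  wl <- default_grid()
  B <- length(wl)
  feats <- config$features
  p <- nrow(feats)
  with_seed(config$seed, {
    dm <- pmin(pmax(config$trait_law$shift +
                      stats::rgamma(n, shape = config$trait_law$shape,
                                    scale = config$trait_law$scale),
                    1e-3), 100 - 1e-3)
    water <- config$water_intercept + config$water_slope * dm +
      stats::rnorm(n, sd = config$water_noise_sd)
    water <- pmin(pmax(water, 0.05), 0.98)
    # feature depths: water-driven exact, dm-driven with driver noise
    depths <- matrix(0, n, p)
    for (j in seq_len(p)) {
      if (feats$driver[j] == "water") {
        depths[, j] <- feats$depth_coef[j] * water
      } else {
        dm_eff <- dm + stats::rnorm(n, sd = config$driver_noise_sd)
        depths[, j] <- feats$depth_coef[j] * pmax(dm_eff, 0)
      }
    }
    # low-order polynomial baseline wiggle in a scaled coordinate t in [-1, 1]
    t <- 2 * (wl - min(wl)) / diff(range(wl)) - 1
    wig <- matrix(stats::rnorm(3 * n, sd = config$baseline_wiggle_sd), n, 3)
    mult <- 1 + stats::rnorm(n, sd = config$mult_noise_sd)
    template <- leaf_template(wl)
    dip <- sapply(seq_len(p), function(j)
      gaussian_dip(wl, feats$center[j], feats$width[j]))  # B x p
    spec <- matrix(rep(template, each = n), n, B)
    spec <- spec - depths %*% t(dip)
    if (config$mode == "nonlinear") {
      i1 <- which(feats$center == 1720)[1]
      i2 <- which(feats$center == 2100)[1]
      if (!is.na(i1) && !is.na(i2)) {
        nl_depth <- config$nl_coef * depths[, i1] * depths[, i2]
        spec <- spec - outer(nl_depth, gaussian_dip(wl, config$nl_center, config$nl_width))
      }
    }
    spec <- spec + wig[, 1] + outer(wig[, 2], t) + outer(wig[, 3], t^2)
    spec <- spec * mult
    if (config$add_noise_sd > 0) {
      spec <- spec + matrix(stats::rnorm(n * B, sd = config$add_noise_sd), n, B)
    }
    spec <- pmin(pmax(spec, 0.001), 1)
    if (config$mode == "null") dm <- dm[sample.int(n)]
    record <- data.frame(dm = dm, water = water, depths,
                         mult = mult, wig0 = wig[, 1], wig1 = wig[, 2], wig2 = wig[, 3])
    names(record)[2 + seq_len(p)] <-
      paste0("depth_", feats$driver, "_", feats$center)
    list(dataset = spectra_dataset(spec, dm, wavelengths = wl), record = record)
  })
}
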