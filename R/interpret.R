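# Diagnostics for a fitted stack: contiguous-band permutation importance on
# the test set and residual-versus-predicted analysis with a local smoother.

#' Contiguous-band permutation importance
#'
#' Tiles the wavelength grid into contiguous bands of `band_nm` nanometres,
#' and for each band jointly permutes the raw reflectance rows of all its
#' wavelengths (one shared row shuffle per repeat, preserving within-band
#' correlation), re-runs the full preprocessing + prediction path, and
#' records the increase in test RMSE. Permutation is applied to raw
#' reflectance before standardization/PCA so importance propagates through
#' the entire pipeline. The grid remainder forms a short final band, flagged
#' in the output.
#'
#' @param model A fitted model with a `predict(model, newdata)` method on
#'   reflectance (e.g. a `dm_stack` or `fitted_learner`).
#' @param test Test [spectra_dataset()] with n >= 5.
#' @param band_nm Band width in nm (default 10).
#' @param repeats Permutation repeats per band (default 10).
#' @param seed Integer seed.
#' @return An `importance_profile` data frame: `start`, `end`, `center` (nm),
#'   `delta_rmse_mean`, `delta_rmse_sd` (DM %), `short` (logical). Attributes:
#'   `baseline_rmse`, `repeats`, `seed`.
#' @export
band_permutation_importance <- function(model, test, band_nm = 10,
                                        repeats = 10, seed = 1) {
  stopifnot(inherits(test, "spectra_dataset"))
  n <- n_samples(test)
  if (n < 5L) stopf("test set needs n >= 5")
  if (repeats < 1L) stopf("`repeats` must be >= 1")
  wl <- test$wl
  if (band_nm > diff(range(wl)) + 1) stopf("band wider than the grid")
  starts <- seq(min(wl), max(wl), by = band_nm)
  baseline_pred <- predict(model, test)
  baseline <- rmse(test$dm, baseline_pred)
  perms <- with_seed(seed, lapply(seq_len(repeats), function(r) sample.int(n)))
  out <- lapply(starts, function(s) {
    e <- min(s + band_nm - 1, max(wl))
    cols <- which(wl >= s & wl <= e)
    dr <- vapply(perms, function(pm) {
      refl <- test$refl
      refl[, cols] <- refl[pm, cols, drop = FALSE]
      rmse(test$dm, predict(model, refl)) - baseline
    }, 0)
    data.frame(start = s, end = e, center = (s + e) / 2,
               delta_rmse_mean = mean(dr),
               delta_rmse_sd = if (repeats > 1) stats::sd(dr) else 0,
               short = (e - s + 1) < band_nm)
  })
  structure(do.call(rbind, out),
            class = c("importance_profile", "data.frame"),
            baseline_rmse = baseline, repeats = repeats, seed = seed)
}

#' @export
print.importance_profile <- function(x, ...) {
  top <- x[order(-x$delta_rmse_mean), ][1:min(5, nrow(x)), ]
  cat(sprintf("Band permutation importance: %d bands, baseline RMSE %.3f%%\n",
              nrow(x), attr(x, "baseline_rmse")))
  cat("Top bands by mean delta RMSE:\n")
  print.data.frame(transform(top, delta_rmse_mean = round(delta_rmse_mean, 4),
                             delta_rmse_sd = round(delta_rmse_sd, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.importance_profile <- function(x, ...) {
  graphics::plot(x$center, x$delta_rmse_mean, type = "h",
                 xlab = "wavelength (nm)", ylab = expression(Delta ~ "RMSE (%)"), ...)
  invisible(x)
}

# Tri-cube weighted local linear regression evaluated at `xout`; span is the
# fraction of points in each local neighborhood.
local_linear_smooth <- function(x, y, xout, span = 0.75) {
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) h <- .Machine$double.eps
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    if (sum(use) < 2L || stats::sd(x[use]) == 0) {
      sum(w * y) / sum(w)
    } else {
      fit <- stats::lm.wfit(cbind(1, x[use]), y[use], w[use])
      fit$coefficients[1] + fit$coefficients[2] * x0
    }
  }, 0)
}

#' Residual diagnostics for a fitted model
#'
#' Residuals (observed - predicted) against predictions on the test set,
#' with a tri-cube weighted local linear smoother evaluated on a uniform grid
#' over the prediction range to expose systematic trends.
#'
#' @param model A fitted model with a `predict` method.
#' @param test Test [spectra_dataset()] with n >= 10.
#' @param span Smoother span in (0, 1\] (default 0.75).
#' @param grid_n Number of smoother evaluation points (default 50).
#' @return A `residual_diagnostics` list: `predicted`, `residuals`,
#'   `smoother` (data frame `x`, `y`), `span`.
#' @export
residual_diagnostics <- function(model, test, span = 0.75, grid_n = 50) {
  stopifnot(inherits(test, "spectra_dataset"))
  if (n_samples(test) < 10L) stopf("test set needs n >= 10 for smoothing")
  if (span <= 0 || span > 1) stopf("`span` must lie in (0, 1]")
  pred <- predict(model, test)
  res <- test$dm - pred
  xout <- seq(min(pred), max(pred), length.out = grid_n)
  sm <- local_linear_smooth(pred, res, xout, span)
  structure(list(predicted = pred, residuals = res,
                 smoother = data.frame(x = xout, y = sm), span = span),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("Residual diagnostics: n = %d, mean residual %.4f%%, sd %.3f%%\n",
              length(x$residuals), mean(x$residuals), stats::sd(x$residuals)))
  cat(sprintf("  smoother range over predictions: [%.3f, %.3f]\n",
              min(x$smoother$y), max(x$smoother$y)))
  invisible(x)
}

#' @export
plot.residual_diagnostics <- function(x, ...) {
  graphics::plot(x$predicted, x$residuals, pch = 16, col = "grey50",
                 xlab = "predicted dry matter (%)", ylab = "residual (%)", ...)
  graphics::lines(x$smoother$x, x$smoother$y, col = "blue", lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
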