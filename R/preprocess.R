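# Preprocessing: artifact screening, optional Savitzky-Golay smoothing,
# train-only standardization and PCA reduction. Fit on training data only;
# apply anywhere.

as_refl_matrix <- function(x) {
  if (inherits(x, "spectra_dataset")) x$refl else as.matrix(x)
}

#' Screen spectra for measurement artifacts
#'
#' Flags samples whose reflectance falls outside the physically plausible
#' range, jumps implausibly between adjacent bands, or contains non-finite
#' values.
#'
#' @param x A [spectra_dataset()] or reflectance matrix.
#' @param max_reflectance Upper plausibility bound (default 1).
#' @param max_abs_step Largest plausible absolute first difference between
#'   adjacent bands (default 0.2).
#' @return An `artifact_report`: data frame with one row per (sample, flag)
#'   listing offending wavelengths; zero rows when all spectra are clean.
#' @export
screen_artifacts <- function(x, max_reflectance = 1, max_abs_step = 0.2) {
  if (max_reflectance <= 0 || max_abs_step <= 0) stopf("thresholds must be > 0")
  refl <- as_refl_matrix(x)
  wl <- if (inherits(x, "spectra_dataset")) x$wl else
    as.integer(sub("^R", "", colnames(refl)))
  ids <- rownames(refl)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(refl)))
  rows <- list()
  for (i in seq_len(nrow(refl))) {
    v <- refl[i, ]
    nf <- which(!is.finite(v))
    if (length(nf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], flag = "non_finite",
        wavelengths = paste(wl[nf], collapse = ";"))
      v[nf] <- NA
    }
    oob <- which(v < 0 | v > max_reflectance)
    if (length(oob)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], flag = "out_of_range",
        wavelengths = paste(wl[oob], collapse = ";"))
    }
    st <- which(abs(diff(v)) > max_abs_step)
    if (length(st)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i], flag = "spike",
        wavelengths = paste(wl[st], collapse = ";"))
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), flag = character(), wavelengths = character())
  structure(report, class = c("artifact_report", "data.frame"),
            thresholds = c(max_reflectance = max_reflectance, max_abs_step = max_abs_step))
}

#' Sample ids flagged by an artifact report
#' @param report An `artifact_report`.
#' @return Character vector of unique flagged sample ids.
#' @export
flagged_ids <- function(report) unique(report$sample_id)

#' Savitzky-Golay smoothing
#'
#' Replaces each band by the center value of a local least-squares quadratic
#' fit over a sliding window. Edges are handled by mirror-padding the
#' spectrum by `(window - 1) / 2` bands so the grid length is preserved.
#'
#' @param x A [spectra_dataset()], reflectance matrix, or numeric vector.
#' @param window Odd window length in bands (the modeling recipe explores
#'   7, 9, 11 and 13).
#' @param polyorder Polynomial order of the local fit (default 2).
#' @return Smoothed object of the same type as `x`.
#' @export
savgol_smooth <- function(x, window, polyorder = 2) {
  if (window %% 2 == 0) stopf("`window` must be odd")
  if (window <= polyorder + 1) stopf("`window` must exceed polyorder + 1")
  if (inherits(x, "spectra_dataset")) {
    sm <- savgol_smooth(x$refl, window, polyorder)
    return(spectra_dataset(sm, x$dm, x$ids, x$wl))
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1L) else as.matrix(x)
  h <- (window - 1L) / 2L
  B <- ncol(m)
  if (window > B) stopf("`window` exceeds the number of bands")
  # mirror padding (reflect without repeating the edge sample)
  pad <- cbind(m[, (h + 1L):2L, drop = FALSE], m, m[, (B - 1L):(B - h), drop = FALSE])
  coefs <- signal::sgolay(p = polyorder, n = window)[h + 1L, ]
  out <- matrix(0, nrow(m), B)
  for (k in seq_len(window)) {
    out <- out + coefs[k] * pad[, k:(k + B - 1L), drop = FALSE]
  }
  dimnames(out) <- dimnames(m)
  if (vec) drop(out) else out
}

#' Fit a per-band standardizer on training spectra
#'
#' Stores per-band means and standard deviations (denominator n - 1) computed
#' from the training set only. Zero-variance bands are excluded from the
#' standardized output and recorded so downstream wavelength bookkeeping stays
#' intact.
#'
#' @param x Training [spectra_dataset()] or reflectance matrix.
#' @return A `standardizer`: list with `mean`, `sd`, `keep` (logical per
#'   band), `wl` (wavelengths of kept bands).
#' @export
fit_standardizer <- function(x) {
  refl <- as_refl_matrix(x)
  wl <- if (inherits(x, "spectra_dataset")) x$wl else
    as.integer(sub("^R", "", colnames(refl)))
  mu <- colMeans(refl)
  sdv <- apply(refl, 2L, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warnf("%d zero-variance band(s) excluded from standardization", sum(!keep))
  }
  structure(list(mean = mu, sd = sdv, keep = keep, wl = wl),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std A `standardizer` from [fit_standardizer()].
#' @param x A [spectra_dataset()] or reflectance matrix on the same grid.
#' @return Matrix of standardized reflectance (zero-variance training bands
#'   dropped); column names carry the wavelengths.
#' @export
apply_standardizer <- function(std, x) {
  stopifnot(inherits(std, "standardizer"))
  refl <- as_refl_matrix(x)
  if (ncol(refl) != length(std$mean)) stopf("grid mismatch between standardizer and data")
  z <- sweep(refl[, std$keep, drop = FALSE], 2L, std$mean[std$keep], `-`)
  sweep(z, 2L, std$sd[std$keep], `/`)
}

#' Fit PCA on standardized training spectra
#'
#' Singular value decomposition of the (column-centered) input. `k_max` is
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target`. Loading signs are fixed so each component's
#' largest-magnitude element is positive, making score signs reproducible.
#'
#' @param z Standardized training matrix (samples x bands).
#' @param variance_target Cumulative explained-variance target in (0, 1\];
#'   default 0.99.
#' @return A `pca_model`: list with `center`, `loadings` (bands x k_max),
#'   `eigenvalues` (all), `explained` (cumulative proportion), `k_max`.
#' @export
fit_pca <- function(z, variance_target = 0.99) {
  if (variance_target <= 0 || variance_target > 1) {
    stopf("`variance_target` must lie in (0, 1]")
  }
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L) stopf("need >= 2 samples for PCA")
  ctr <- colMeans(z)
  zc <- sweep(z, 2L, ctr, `-`)
  sv <- svd(zc)
  eig <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  eig_r <- eig[seq_len(rank)]
  cum <- cumsum(eig_r) / sum(eig_r)
  k_max <- which(cum >= variance_target)[1]
  V <- sv$v[, seq_len(k_max), drop = FALSE]
  # deterministic sign: largest-magnitude loading element positive
  for (j in seq_len(k_max)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(z)
  structure(list(center = ctr, loadings = V, eigenvalues = eig_r,
                 explained = cum, k_max = k_max),
            class = "pca_model")
}

#' Project spectra onto fitted principal components
#'
#' @param pca A `pca_model` from [fit_pca()].
#' @param z Standardized matrix on the same bands.
#' @param k Number of components (default `k_max`).
#' @return Score matrix (samples x k).
#' @export
pca_project <- function(pca, z, k = pca$k_max) {
  stopifnot(inherits(pca, "pca_model"))
  if (k < 1L || k > pca$k_max) stopf("`k` must lie in [1, %d]", pca$k_max)
  z <- as.matrix(z)
  if (ncol(z) != length(pca$center)) stopf("band mismatch between PCA model and data")
  sweep(z, 2L, pca$center, `-`) %*% pca$loadings[, seq_len(k), drop = FALSE]
}

#' Preprocessing options
#'
#' @param sg_window Savitzky-Golay window (0 disables smoothing, the
#'   default, since smoothing did not help cross-validated accuracy on
#'   laboratory-quality spectra).
#' @param variance_target PCA cumulative explained-variance target.
#' @param pca_refit `"fold"` (refit standardizer + PCA inside every CV
#'   training fold; the leakage-conservative default) or `"train"` (fit once
#'   on the full training set).
#' @return A `prep_opts` list.
#' @export
prep_opts <- function(sg_window = 0, variance_target = 0.99,
                      pca_refit = c("fold", "train")) {
  pca_refit <- match.arg(pca_refit)
  if (!sg_window %in% c(0, 7, 9, 11, 13) && (sg_window %% 2 == 0 || sg_window < 5)) {
    stopf("`sg_window` must be 0 (off) or an odd window >= 5")
  }
  structure(list(sg_window = sg_window, variance_target = variance_target,
                 pca_refit = pca_refit), class = "prep_opts")
}

#' Fit the full preprocessing model (smoothing + standardizer + PCA)
#'
#' @param train Training [spectra_dataset()] or reflectance matrix.
#' @param opts A [prep_opts()].
#' @return A `prep_model` with elements `opts`, `std`, `pca`.
#' @export
fit_preprocess <- function(train, opts = prep_opts()) {
  refl <- as_refl_matrix(train)
  if (opts$sg_window > 0) refl <- savgol_smooth(refl, opts$sg_window)
  std <- fit_standardizer(refl)
  pca <- fit_pca(apply_standardizer(std, refl), opts$variance_target)
  structure(list(opts = opts, std = std, pca = pca), class = "prep_model")
}

#' Transform spectra through a fitted preprocessing model
#'
#' @param prep A `prep_model` from [fit_preprocess()].
#' @param x A [spectra_dataset()] or reflectance matrix.
#' @param k Number of PCA components for `output = "scores"`.
#' @param output `"scores"` (PCA scores) or `"standardized"` (standardized
#'   bands, no projection).
#' @return Numeric matrix.
#' @export
transform_spectra <- function(prep, x, k = prep$pca$k_max,
                              output = c("scores", "standardized")) {
  stopifnot(inherits(prep, "prep_model"))
  output <- match.arg(output)
  refl <- as_refl_matrix(x)
  if (prep$opts$sg_window > 0) refl <- savgol_smooth(refl, prep$opts$sg_window)
  z <- apply_standardizer(prep$std, refl)
  if (output == "standardized") z else pca_project(prep$pca, z, k)
}
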