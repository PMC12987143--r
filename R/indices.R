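# Spectral index library and the two index-based baselines: single-index
# ordinary least squares and elastic net on the standardized index table.

index_def <- function(name, kind, wavelengths, fun) {
  list(name = name, kind = kind, wavelengths = wavelengths, fun = fun)
}

nd <- function(a, b) (a - b) / (a + b)

# The 23 printed definitions plus the NWI 970/900 variant named in published
# index-combination models. The literature sometimes counts 26 narrow-band
# indices for this task; the three further definitions are not printed
# anywhere reproducible, so the registry ships these 24 and is extensible.
.index_registry <- list(
  index_def("NDII", "normalized_difference", c(820, 1600),
            function(R) nd(R(820), R(1600))),
  index_def("WI", "ratio", c(900, 970), function(R) R(900) / R(970)),
  index_def("SRWI", "ratio", c(860, 1240), function(R) R(860) / R(1240)),
  index_def("LWI", "ratio", c(1300, 1450), function(R) R(1300) / R(1450)),
  index_def("NDLI", "log_normalized_difference", c(1680, 1754),
            function(R) nd(log10(1 / R(1680)), log10(1 / R(1754)))),
  index_def("CAI", "linear_combination", c(2000, 2100, 1900),
            function(R) R(2000) - 0.5 * (R(2100) + R(1900))),
  index_def("NDWI1640", "normalized_difference", c(858, 1640),
            function(R) nd(R(858), R(1640))),
  index_def("NDWI", "normalized_difference", c(860, 1240),
            function(R) nd(R(860), R(1240))),
  index_def("NDVI", "normalized_difference", c(760, 670),
            function(R) nd(R(760), R(670))),
  index_def("NWI", "normalized_difference", c(970, 900),
            function(R) nd(R(970), R(900))),
  index_def("SWSI1", "composite", c(803, 681, 905, 972),
            function(R) (R(803) - R(681)) / (R(905) + R(972))),
  index_def("SWSI2", "composite", c(803, 681, 1326, 1507),
            function(R) (R(803) - R(681)) / (R(1326) + R(1507))),
  index_def("SWSI3", "composite", c(803, 681, 972, 1174),
            function(R) (R(803) - R(681)) / (R(972) + R(1174))),
  index_def("MSI", "ratio", c(1600, 820), function(R) R(1600) / R(820)),
  index_def("NDII2", "normalized_difference", c(819, 1649),
            function(R) nd(R(819), R(1649))),
  index_def("NDWI_Hyp", "normalized_difference", c(1070, 1200),
            function(R) nd(R(1070), R(1200))),
  index_def("DWSI1", "ratio", c(800, 1660), function(R) R(800) / R(1660)),
  index_def("DWSI2", "ratio", c(1660, 550), function(R) R(1660) / R(550)),
  index_def("DWSI3", "ratio", c(1600, 680), function(R) R(1600) / R(680)),
  index_def("DWSI4", "ratio", c(550, 680), function(R) R(550) / R(680)),
  index_def("DWSI5", "composite", c(800, 550, 1660, 680),
            function(R) (R(800) - R(550)) / (R(1660) + R(680))),
  index_def("NDMI", "normalized_difference", c(1649, 1720),
            function(R) nd(R(1649), R(1720))),
  index_def("DMCI", "normalized_difference", c(2305, 1495),
            function(R) nd(R(2305), R(1495))),
  index_def("NWI_970_900", "normalized_difference", c(900, 970),
            function(R) nd(R(900), R(970)))
)
names(.index_registry) <- vapply(.index_registry, `[[`, "", "name")

#' Spectral index registry
#'
#' Narrow-band reflectance indices and SWIR structural proxies used as dry
#' matter predictors: normalized differences (NDII, NDWI variants, NDVI, NWI,
#' NDMI, DMCI, ...), pure ratios (WI, SRWI, LWI, MSI, DWSI-1..4), the
#' log-ratio NDLI, the linear-combination CAI and composite SWSI/DWSI-5
#' forms.
#'
#' @return Data frame with columns `name`, `kind`, `wavelengths`
#'   (semicolon-separated nm).
#' @export
spectral_indices <- function() {
  data.frame(
    name = vapply(.index_registry, `[[`, "", "name"),
    kind = vapply(.index_registry, `[[`, "", "kind"),
    wavelengths = vapply(.index_registry, function(d)
      paste(d$wavelengths, collapse = ";"), ""),
    row.names = NULL
  )
}

get_index_def <- function(name) {
  def <- .index_registry[[name]]
  if (is.null(def)) stopf("unknown index '%s'; see spectral_indices()", name)
  def
}

band_getter <- function(x) {
  refl <- as_refl_matrix(x)
  wl <- if (inherits(x, "spectra_dataset")) x$wl else
    as.integer(sub("^R", "", colnames(refl)))
  function(lambda) {
    j <- which(wl == lambda)
    if (!length(j)) {
      j <- which.min(abs(wl - lambda))
      if (abs(wl[j] - lambda) > 1) stopf("wavelength %d nm not on grid", lambda)
    }
    refl[, j]
  }
}

#' Compute one spectral index
#'
#' Evaluates the printed formula elementwise. Wavelengths are matched exactly
#' on the 1 nm grid (nearest neighbor within 1 nm otherwise). Samples with a
#' zero denominator yield `NA` with a warning and are excluded from
#' downstream regressions rather than aborting the run.
#'
#' @param x A [spectra_dataset()] or reflectance matrix.
#' @param name Index name from [spectral_indices()].
#' @return Numeric vector, one value per sample.
#' @export
compute_index <- function(x, name) {
  def <- if (is.list(name) && !is.null(name$fun)) name else get_index_def(name)
  v <- def$fun(band_getter(x))
  bad <- !is.finite(v)
  if (any(bad)) {
    warnf("index %s non-finite for %d sample(s); set to NA", def$name, sum(bad))
    v[bad] <- NA_real_
  }
  unname(v)
}

#' Compute the full index table
#'
#' @param x A [spectra_dataset()] or reflectance matrix.
#' @param names Index names (default: the whole registry).
#' @return Matrix (samples x indices).
#' @export
compute_index_table <- function(x, names = spectral_indices()$name) {
  vals <- vapply(names, function(nm) compute_index(x, nm),
                 numeric(nrow(as_refl_matrix(x))))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names))
  vals
}

#' Single-index linear baseline
#'
#' Ordinary least squares of dry matter on one index, coefficients estimated
#' on the training set only, evaluated on the test set.
#'
#' @param train,test [spectra_dataset()]s.
#' @param name Index name.
#' @return List with `rmse`, `r2`, `slope`, `intercept`, `n_used`.
#' @export
single_index_baseline <- function(train, test, name) {
  xtr <- compute_index(train, name)
  xte <- compute_index(test, name)
  ok <- is.finite(xtr)
  if (stats::sd(xtr[ok]) == 0) stopf("index %s has zero variance on training data", name)
  fit <- stats::lm.fit(cbind(1, xtr[ok]), train$dm[ok])
  b <- fit$coefficients
  ok_te <- is.finite(xte)
  pred <- b[1] + b[2] * xte[ok_te]
  list(rmse = rmse(test$dm[ok_te], pred), r2 = rsq(test$dm[ok_te], pred),
       slope = unname(b[2]), intercept = unname(b[1]), n_used = sum(ok_te))
}

#' Benchmark all indices as single predictors
#'
#' @param train,test [spectra_dataset()]s.
#' @param names Index names (default: whole registry).
#' @return Data frame (index, rmse, r2) sorted by decreasing test R^2.
#' @export
index_benchmark <- function(train, test, names = spectral_indices()$name) {
  rows <- lapply(names, function(nm) {
    res <- single_index_baseline(train, test, nm)
    data.frame(index = nm, rmse = res$rmse, r2 = res$r2)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r2), , drop = FALSE]
}

#' Elastic net on standardized spectral indices
#'
#' Fits an elastic net to the full index table, standardized to zero mean and
#' unit variance using training statistics so coefficients are directly
#' comparable in magnitude. The penalty `lambda` and mixture `alpha` are
#' tuned by seeded k-fold cross-validation on the training set.
#'
#' @param train,test [spectra_dataset()]s.
#' @param names Index names (default: whole registry).
#' @param alphas Mixture grid searched (0 = ridge, 1 = lasso).
#' @param folds CV folds.
#' @param seed Integer seed for the fold assignment.
#' @return An `enet_indices` object: standardized coefficients, intercept,
#'   chosen `alpha`/`lambda`, retained index names, test `rmse`/`r2`.
#' @export
enet_on_indices <- function(train, test, names = spectral_indices()$name,
                            alphas = seq(0, 1, by = 0.25), folds = 10, seed = 1) {
  if (length(names) < 2L) stopf("need at least 2 indices")
  xtr <- compute_index_table(train, names)
  xte <- compute_index_table(test, names)
  ok <- stats::complete.cases(xtr)
  xtr <- xtr[ok, , drop = FALSE]
  ytr <- train$dm[ok]
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2L, stats::sd)
  if (any(sdv == 0)) stopf("index with zero training variance: %s",
                           paste(names[sdv == 0], collapse = ", "))
  ztr <- scale(xtr, mu, sdv)
  zte <- scale(xte, mu, sdv)
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(ztr))))
  cvs <- lapply(alphas, function(a)
    glmnet::cv.glmnet(ztr, ytr, alpha = a, foldid = foldid, standardize = FALSE))
  best_cv <- vapply(cvs, function(cv) min(cv$cvm), 0)
  pick <- which.min(best_cv)
  cv <- cvs[[pick]]
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(ztr))
  coefs <- beta[-1]
  if (all(coefs == 0)) warnf("all index coefficients shrunk to zero; intercept-only model")
  ok_te <- stats::complete.cases(zte)
  pred <- beta[1] + as.numeric(zte[ok_te, , drop = FALSE] %*% coefs)
  structure(list(
    coefficients = coefs[order(-abs(coefs))], intercept = unname(beta[1]),
    alpha = alphas[pick], lambda = cv$lambda.min,
    retained = names(coefs)[coefs != 0],
    rmse = rmse(test$dm[ok_te], pred), r2 = rsq(test$dm[ok_te], pred),
    predictions = pred
  ), class = "enet_indices")
}

#' @export
print.enet_indices <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  terms <- sprintf("%+0.2f %s", nz, names(nz))
  cat("Elastic net on standardized spectral indices\n")
  cat(sprintf("  DM^ = %.2f %s\n", x$intercept, paste(terms, collapse = " ")))
  cat(sprintf("  alpha = %.2f, lambda = %.4g; retained %d of %d indices\n",
              x$alpha, x$lambda, length(x$retained), length(x$coefficients)))
  cat(sprintf("  test RMSE = %.3f%%, R2 = %.3f\n", x$rmse, x$r2))
  invisible(x)
}
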