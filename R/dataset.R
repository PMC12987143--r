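# Spectra data model, dry-matter computation, wide-CSV I/O, dataset splitting
# and train/test comparability statistics.

#' Default wavelength grid
#'
#' The full-range grid used throughout the package: every integer wavelength
#' from 350 to 2500 nm (2151 bands).
#'
#' @return Integer vector of wavelengths in nm.
#' @export
default_grid <- function() 350:2500

validate_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L) {
    stopf("wavelength grid must be a numeric vector of length >= 2")
  }
  w <- as.integer(wavelengths)
  if (any(w != wavelengths)) stopf("wavelengths must be integers (nm)")
  if (anyDuplicated(w)) stopf("wavelength grid contains duplicates")
  if (any(diff(w) <= 0)) stopf("wavelength grid must be strictly increasing")
  w
}

#' Construct a spectra dataset
#'
#' Bundles a reflectance matrix (one row per leaf sample, one column per
#' wavelength) with the measured dry matter content of each sample.
#'
#' @param reflectance Numeric matrix, n samples x B wavelengths; unitless
#'   reflectance fractions. All values must be finite.
#' @param dm Numeric vector of dry matter content in percent, one value per
#'   row of `reflectance`; must lie in \[0, 100\].
#' @param sample_id Optional character vector of unique sample identifiers;
#'   defaults to `"s1", "s2", ...`.
#' @param wavelengths Integer wavelengths (nm) of the columns; defaults to
#'   [default_grid()] when the column count matches.
#' @return An object of class `spectra_dataset`: a list with elements
#'   `refl` (matrix), `dm` (numeric), `ids` (character), `wl` (integer).
#' @export
spectra_dataset <- function(reflectance, dm, sample_id = NULL, wavelengths = NULL) {
  if (!is.matrix(reflectance)) reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  if (is.null(wavelengths)) {
    if (ncol(reflectance) == length(default_grid())) {
      wavelengths <- default_grid()
    } else {
      stopf("`wavelengths` must be given when reflectance has %d != %d columns",
            ncol(reflectance), length(default_grid()))
    }
  }
  wl <- validate_grid(wavelengths)
  if (ncol(reflectance) != length(wl)) {
    stopf("reflectance has %d columns but grid has %d wavelengths",
          ncol(reflectance), length(wl))
  }
  if (!all(is.finite(reflectance))) {
    bad <- which(!apply(is.finite(reflectance), 1L, all))
    stopf("non-finite reflectance in rows: %s", paste(utils::head(bad, 10), collapse = ", "))
  }
  if (length(dm) != n) stopf("`dm` length %d does not match %d samples", length(dm), n)
  if (!all(is.finite(dm)) || any(dm < 0 | dm > 100)) {
    stopf("dry matter values must be finite and within [0, 100] percent")
  }
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n) stopf("`sample_id` length mismatch")
  if (anyDuplicated(sample_id)) stopf("sample ids must be unique")
  dimnames(reflectance) <- list(sample_id, paste0("R", wl))
  structure(
    list(refl = reflectance, dm = stats::setNames(as.numeric(dm), sample_id),
         ids = sample_id, wl = wl),
    class = "spectra_dataset"
  )
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d samples x %d bands (%d-%d nm)\n",
              length(x$ids), length(x$wl), min(x$wl), max(x$wl)))
  cat(sprintf("  dry matter: mean %.2f%%, range [%.2f, %.2f]\n",
              mean(x$dm), min(x$dm), max(x$dm)))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds A `spectra_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) length(ds$ids)

#' Subset a spectra dataset by row
#' @param x A `spectra_dataset`.
#' @param i Row index (integer, logical, or sample id character).
#' @param ... Ignored.
#' @return A `spectra_dataset` containing the selected samples.
#' @export
`[.spectra_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  spectra_dataset(x$refl[i, , drop = FALSE], x$dm[i], x$ids[i], x$wl)
}

#' Compute dry matter content from fresh and dry mass
#'
#' DM (%) = 100 * m_dry / m_fresh, the fraction of leaf fresh mass remaining
#' after oven drying.
#'
#' @param mfresh Fresh mass (g), must be > 0. Vectorized.
#' @param mdry Dry mass (g), must satisfy 0 <= mdry <= mfresh.
#' @return Dry matter content in percent.
#' @examples
#' compute_dm(10, 2)   # 20
#' @export
compute_dm <- function(mfresh, mdry) {
  if (length(mfresh) != length(mdry)) stopf("mass vectors must have equal length")
  if (!all(is.finite(mfresh)) || !all(is.finite(mdry))) stopf("masses must be finite")
  if (any(mfresh <= 0)) stopf("`mfresh` must be > 0")
  if (any(mdry < 0)) stopf("`mdry` must be >= 0")
  if (any(mdry > mfresh)) stopf("`mdry` cannot exceed `mfresh`")
  100 * mdry / mfresh
}

#' Read a wide-format spectra CSV
#'
#' Expected header: `sample_id`, then either `dm` (percent) or the mass pair
#' `mfresh`,`mdry`, then one reflectance column per grid wavelength named
#' `R<wavelength>` (e.g. `R350` ... `R2500`). Column order is normalized to
#' ascending wavelength. When both `dm` and the mass pair are present, `dm`
#' takes precedence.
#'
#' @param path CSV file path.
#' @param wavelengths Expected wavelength grid; defaults to [default_grid()].
#' @return A [spectra_dataset()].
#' @export
read_spectra_csv <- function(path, wavelengths = default_grid()) {
  wl <- validate_grid(wavelengths)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (!"sample_id" %in% names(dt)) stopf("missing `sample_id` column")
  rcols <- grep("^R[0-9]+$", names(dt), value = TRUE)
  got <- as.integer(sub("^R", "", rcols))
  missing_wl <- setdiff(wl, got)
  extra_wl <- setdiff(got, wl)
  if (length(missing_wl)) {
    stopf("schema error: %d wavelength columns missing (first: R%d)",
          length(missing_wl), missing_wl[1])
  }
  if (length(extra_wl)) {
    stopf("schema error: columns off the %d-%d nm grid: %s",
          min(wl), max(wl), paste0("R", utils::head(extra_wl, 5), collapse = ", "))
  }
  if ("dm" %in% names(dt)) {
    dm <- dt$dm
  } else if (all(c("mfresh", "mdry") %in% names(dt))) {
    dm <- compute_dm(dt$mfresh, dt$mdry)
  } else {
    stopf("missing `dm` column (or `mfresh`/`mdry` pair)")
  }
  refl <- as.matrix(dt[, paste0("R", wl)])  # normalizes to ascending order
  if (anyNA(refl) || !all(is.finite(refl))) {
    bad <- which(!apply(is.finite(refl), 1L, all))
    stopf("data error: non-finite reflectance in rows: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  spectra_dataset(refl, dm, dt$sample_id, wl)
}

#' Write a spectra dataset as wide CSV
#'
#' Inverse of [read_spectra_csv()]; round-trips reflectance to full double
#' precision.
#'
#' @param ds A `spectra_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  out <- data.frame(sample_id = ds$ids, dm = unname(ds$dm),
                    ds$refl, check.names = FALSE)
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' Split a dataset into training and test subsets
#'
#' Seeded uniform random partition. The training set receives
#' `floor(train_frac * n)` samples; the remainder forms the test set. The same
#' seed always reproduces the same partition.
#'
#' @param ds A `spectra_dataset`.
#' @param train_frac Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both `spectra_dataset`s.
#' @export
split_dataset <- function(ds, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(ds, "spectra_dataset"))
  n <- n_samples(ds)
  if (n < 2L) stopf("need at least 2 samples to split")
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stopf("`train_frac` must lie strictly between 0 and 1")
  }
  n_train <- floor(train_frac * n)
  if (n_train < 1L || n_train >= n) stopf("split leaves an empty subset")
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = ds[sort(idx)], test = ds[sort(setdiff(seq_len(n), idx))])
}

# Bias-corrected (adjusted) sample skewness/kurtosis; e1071 type 2 matches the
# usual "adjusted Fisher-Pearson" estimators.
sample_skewness <- function(x) e1071::skewness(x, type = 2)
sample_kurtosis <- function(x) e1071::kurtosis(x, type = 2)

describe_group <- function(y) {
  constant <- stats::sd(y) == 0
  data.frame(
    n = length(y), mean = mean(y), median = stats::median(y),
    sd = stats::sd(y), min = min(y), max = max(y),
    skew = if (constant) NA_real_ else sample_skewness(y),
    kurt = if (constant) NA_real_ else sample_kurtosis(y)
  )
}

#' Train/test comparability statistics for the dry matter trait
#'
#' Descriptive statistics per subset plus three two-group checks: Shapiro-Wilk
#' normality within each subset, Fligner-Killeen homogeneity of variances, and
#' the Wilcoxon rank-sum (Mann-Whitney) location test. Skewness and kurtosis
#' use the adjusted (bias-corrected) estimators.
#'
#' @param train_dm,test_dm Numeric dry matter vectors (percent) for the two
#'   subsets; each needs n >= 3 for descriptives and n >= 8 for the tests.
#' @return An object of class `cohort_stats`: list with `descriptives`
#'   (two-row data frame) and `tests` (data frame of statistic/p per test).
#' @export
cohort_stats <- function(train_dm, test_dm) {
  if (length(train_dm) < 3L || length(test_dm) < 3L) {
    stopf("need n >= 3 per group for descriptive statistics")
  }
  desc <- rbind(describe_group(train_dm), describe_group(test_dm))
  rownames(desc) <- c("train", "test")
  tests <- NULL
  if (stats::sd(train_dm) == 0 || stats::sd(test_dm) == 0) {
    warnf("constant dry matter vector: comparability tests skipped")
  } else if (length(train_dm) < 8L || length(test_dm) < 8L) {
    warnf("need n >= 8 per group for comparability tests; tests skipped")
  } else {
    sw_tr <- stats::shapiro.test(train_dm)
    sw_te <- stats::shapiro.test(test_dm)
    fk <- stats::fligner.test(list(train_dm, test_dm))
    wt <- suppressWarnings(stats::wilcox.test(train_dm, test_dm))
    tests <- data.frame(
      test = c("shapiro_train", "shapiro_test", "fligner_killeen", "wilcoxon_rank_sum"),
      statistic = c(sw_tr$statistic, sw_te$statistic, fk$statistic, wt$statistic),
      p_value = c(sw_tr$p.value, sw_te$p.value, fk$p.value, wt$p.value),
      row.names = NULL
    )
  }
  structure(list(descriptives = desc, tests = tests,
                 estimators = "skewness/kurtosis: adjusted (bias-corrected, e1071 type 2)"),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Dry matter comparability report\n\nDescriptive statistics (%):\n")
  print(round(x$descriptives, 3))
  if (!is.null(x$tests)) {
    cat("\nTwo-group tests:\n")
    print(transform(x$tests, statistic = signif(statistic, 5),
                    p_value = signif(p_value, 4)))
  } else {
    cat("\n(tests skipped)\n")
  }
  invisible(x)
}
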