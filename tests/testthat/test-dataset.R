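# Data model: DM computation, CSV round-trip, splitting, cohort statistics.

test_that("compute_dm implements the gravimetric formula with its limits", {
  expect_equal(compute_dm(10, 2), 20)
  expect_equal(compute_dm(5, 5), 100)
  expect_equal(compute_dm(3, 0), 0)
  expect_error(compute_dm(0, 0), "mfresh")
  expect_error(compute_dm(-1, 0), "mfresh")
  expect_error(compute_dm(2, 3), "exceed")
  # scale invariance: only the mass ratio matters
  f <- c(3.2, 10, 0.7); d <- c(0.5, 2.5, 0.7)
  for (c_ in c(0.1, 3, 1e4)) {
    expect_equal(compute_dm(c_ * f, c_ * d), compute_dm(f, d))
  }
})

test_that("wide CSV round-trips a dataset and rejects schema violations", {
  ds <- quick_ds(n = 3, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, f)
  back <- read_spectra_csv(f)
  expect_equal(n_samples(back), 3)
  expect_equal(length(back$wl), 2151)
  expect_equal(back$ids, ds$ids)
  expect_lt(max(abs(back$refl - ds$refl)), 1e-9)
  expect_equal(unname(back$dm), unname(ds$dm), tolerance = 1e-9)

  # off-grid column is a schema error
  dt <- data.table::fread(f)
  data.table::setnames(dt, "R2500", "R9999")
  f2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, f2)
  expect_error(read_spectra_csv(f2), "schema")

  # NaN cells are a data error naming the rows
  dt2 <- data.table::fread(f)
  dt2[2, "R400"] <- NaN
  f3 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt2, f3)
  expect_error(read_spectra_csv(f3), "rows: 2")
})

test_that("DM can be loaded from mass columns, with percent taking precedence", {
  ds <- quick_ds(n = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, f)
  dt <- data.table::fread(f)
  dt$mfresh <- c(10, 10, 10)
  dt$mdry <- c(2, 3, 4)
  # dm present: wins over mass pair
  f1 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, f1)
  expect_equal(unname(read_spectra_csv(f1)$dm), unname(ds$dm), tolerance = 1e-9)
  # dm absent: computed from masses
  dt$dm <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, f2)
  expect_equal(unname(read_spectra_csv(f2)$dm), c(20, 30, 40))
})

test_that("split_dataset produces the expected disjoint exhaustive partition", {
  ds <- quick_ds(n = 481, seed = 2)
  sp <- split_dataset(ds, 0.8, seed = 2025)
  expect_equal(n_samples(sp$train), 384)
  expect_equal(n_samples(sp$test), 97)
  # partition property over several seeds and fractions
  small <- quick_ds(n = 50, seed = 3)
  for (s in 1:4) {
    for (fr in c(0.5, 0.8)) {
      p <- split_dataset(small, fr, seed = s)
      expect_equal(n_samples(p$train), floor(fr * 50))
      expect_length(intersect(p$train$ids, p$test$ids), 0)
      expect_setequal(c(p$train$ids, p$test$ids), small$ids)
    }
  }
  # determinism
  expect_identical(split_dataset(small, 0.8, 7)$train$ids,
                   split_dataset(small, 0.8, 7)$train$ids)
  expect_equal(n_samples(split_dataset(small[1:10], 0.8, 1)$train), 8)
  expect_error(split_dataset(small[1], 0.8, 1), "at least 2")
})

test_that("cohort statistics match direct moment-formula oracles", {
  cs <- suppressWarnings(cohort_stats(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)))
  expect_equal(cs$descriptives["train", "mean"], 3)
  expect_equal(cs$descriptives["train", "median"], 3)
  expect_equal(cs$descriptives["train", "min"], 1)
  expect_equal(cs$descriptives["train", "max"], 5)

  # adjusted skewness/kurtosis against the explicit moment formulas
  y <- c(1, 2, 3, 4, 10)
  n <- length(y)
  m2 <- mean((y - mean(y))^2); m3 <- mean((y - mean(y))^3); m4 <- mean((y - mean(y))^4)
  g1 <- m3 / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- m4 / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  cs2 <- suppressWarnings(cohort_stats(y, y))
  expect_equal(cs2$descriptives["train", "skew"], G1, tolerance = 1e-12)
  expect_equal(cs2$descriptives["train", "kurt"], G2, tolerance = 1e-12)
})

test_that("rank-sum p-value for identical groups agrees with exact enumeration", {
  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 4)
  cs <- cohort_stats(c(a, 5, 6, 7, 8), c(b, 5, 6, 7, 8))
  p_pkg <- cs$tests$p_value[cs$tests$test == "wilcoxon_rank_sum"]

  # brute-force oracle: enumerate all group assignments of the pooled
  # midranks and compute the two-sided probability of a rank sum at least as
  # extreme as observed
  pool <- c(a, 5, 6, 7, 8, b, 5, 6, 7, 8)
  rk <- rank(pool)
  n1 <- 8
  combs <- utils::combn(length(pool), n1)
  sums <- apply(combs, 2, function(i) sum(rk[i]))
  obs <- sum(rk[seq_len(n1)])
  ew <- mean(sums)
  p_exact <- mean(abs(sums - ew) >= abs(obs - ew) - 1e-9)
  expect_gt(p_pkg, 0.8)
  expect_lt(abs(p_pkg - p_exact), 0.15)
})

test_that("degenerate cohort inputs are flagged rather than failing", {
  expect_warning(cs <- cohort_stats(rep(5, 10), c(1:10)), "skipped")
  expect_true(is.na(cs$descriptives["train", "skew"]))
  expect_null(cs$tests)
})
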