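# Preprocessing: artifact screen, Savitzky-Golay, standardizer, PCA.

test_that("artifact screen flags the three failure modes and nothing else", {
  ds <- quick_ds(n = 5, seed = 9)
  expect_length(flagged_ids(screen_artifacts(ds)), 0)

  bad <- ds$refl
  bad[2, 100] <- 5.0
  rep1 <- screen_artifacts(spectra_dataset(bad, ds$dm, ds$ids, ds$wl))
  expect_true(any(rep1$flag == "out_of_range" & rep1$sample_id == "s2"))
  expect_match(rep1$wavelengths[rep1$flag == "out_of_range"], "449")

  bad2 <- ds$refl
  bad2[3, 1000] <- bad2[3, 999] + 0.5
  rep2 <- screen_artifacts(spectra_dataset(bad2, ds$dm, ds$ids, ds$wl),
                           max_abs_step = 0.2)
  expect_true(any(rep2$flag == "spike" & rep2$sample_id == "s3"))
})

test_that("Savitzky-Golay reproduces quadratics and matches a refit oracle", {
  wl <- default_grid()
  # exact quadratic in wavelength: invariant at interior bands
  quad <- 0.2 + 1e-4 * (wl - 1000) + 1e-8 * (wl - 1000)^2
  sm <- savgol_smooth(quad, window = 9)
  interior <- 5:(length(wl) - 4)
  expect_lt(max(abs(sm[interior] - quad[interior])), 1e-10)

  # constant spectrum: unchanged everywhere (mirror padding included)
  expect_equal(savgol_smooth(rep(0.4, 2151), 11), rep(0.4, 2151))

  # random spectrum vs per-window explicit quadratic least-squares refit
  x <- specstack:::with_seed(7, runif(200))
  sm9 <- savgol_smooth(x, 9)
  h <- 4
  pad <- c(x[(h + 1):2], x, x[(199):(200 - h)])
  oracle <- vapply(seq_along(x), function(j) {
    win <- pad[j:(j + 2 * h)]
    t <- (-h):h
    unname(coef(lm(win ~ t + I(t^2)))[1])
  }, 0)
  expect_lt(max(abs(sm9 - oracle)), 1e-10)

  expect_error(savgol_smooth(x, 8), "odd")
})

test_that("standardizer uses train-only n-1 statistics", {
  tr <- quick_ds(n = 30, seed = 3)
  std <- fit_standardizer(tr)
  z <- apply_standardizer(std, tr)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)

  # 2x2 hand oracle: train values {0, 2} at one band
  m <- matrix(c(0, 2, 1, 1), 2, 2, dimnames = list(NULL, c("R350", "R351")))
  m2 <- suppressWarnings(fit_standardizer(m))
  expect_equal(unname(m2$mean[1]), 1)
  expect_equal(unname(m2$sd[1]), sqrt(2))     # n-1 denominator
  z4 <- apply_standardizer(m2, matrix(c(4, 1), 1, 2))
  expect_equal(unname(z4[1, 1]), (4 - 1) / sqrt(2))
  # constant training band excluded with warning
  expect_false(m2$keep[2])
  expect_equal(ncol(z4), 1)

  # test band constant at the training mean maps to zeros
  te <- tr$refl
  te[, 5] <- std$mean[5]
  expect_true(all(apply_standardizer(std, te)[, 5] == 0))
})

test_that("PCA recovers exact low rank and conserves variance", {
  set.seed(10)
  u <- qr.Q(qr(cbind(1, matrix(rnorm(40), 20, 2))))[, 2:3]  # orthonormal, mean 0
  v <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  x <- u %*% diag(c(3, 2)) %*% t(v)   # exactly rank 2, balanced spectrum
  p <- fit_pca(x, variance_target = 0.99)
  expect_equal(p$k_max, 2)
  sc <- pca_project(p, x)
  recon <- sweep(sc %*% t(p$loadings), 2, p$center, `+`)
  expect_lt(max(abs(recon - x)), 1e-8)

  # trace conservation on standardized data
  tr <- quick_ds(n = 40, seed = 6)
  z <- apply_standardizer(fit_standardizer(tr), tr)
  p2 <- fit_pca(z, 0.999)
  expect_lt(abs(sum(p2$eigenvalues) - sum(apply(z, 2, var))), 1e-6)
  # loadings orthonormal, eigenvalues non-increasing
  g <- crossprod(p2$loadings)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  expect_true(all(diff(p2$eigenvalues) <= 1e-12))
})

test_that("PCA loadings match an analytic eigen-decomposition", {
  # target covariance [[4,1,0],[1,4,0],[0,0,2]]: eigenvalues 5, 3, 2 with
  # eigenvectors (1,1,0)/sqrt(2), (1,-1,0)/sqrt(2), (0,0,1)
  V <- cbind(c(1, 1, 0) / sqrt(2), c(1, -1, 0) / sqrt(2), c(0, 0, 1))
  lam <- c(5, 3, 2)
  n <- 12
  set.seed(4)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]  # orthonormal, mean 0
  x <- q %*% diag(sqrt((n - 1) * lam)) %*% t(V)
  p <- fit_pca(x, variance_target = 1)
  expect_equal(p$eigenvalues, lam, tolerance = 1e-8)
  for (j in 1:3) {
    expect_lt(min(sum(abs(p$loadings[, j] - V[, j])),
                  sum(abs(p$loadings[, j] + V[, j]))), 1e-8)
  }
})

test_that("projection is linear and k_max grows with the variance target", {
  tr <- quick_ds(n = 30, seed = 12)
  z <- apply_standardizer(fit_standardizer(tr), tr)
  p <- fit_pca(z, 0.99)
  zc <- sweep(z, 2, colMeans(z))
  a <- 2.5; b <- -1
  lhs <- pca_project(p, a * zc[1:5, ] + b * zc[6:10, ] +
                       matrix(p$center, 5, ncol(z), byrow = TRUE))
  rhs <- a * pca_project(p, zc[1:5, ] + matrix(p$center, 5, ncol(z), byrow = TRUE)) +
    b * pca_project(p, zc[6:10, ] + matrix(p$center, 5, ncol(z), byrow = TRUE))
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_lte(fit_pca(z, 0.99)$k_max, fit_pca(z, 0.999)$k_max)
  expect_error(pca_project(p, z, k = p$k_max + 1), "k")
})
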