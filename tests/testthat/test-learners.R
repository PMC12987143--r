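# Learner zoo: search spaces, CV tuning, one-SE selection, evaluation.

test_that("hyperparameter spaces respect the documented bounds", {
  bounds <- list(
    pcr = list(num_comp = c(10, 150)),
    plsr = list(num_comp = c(2, 120)),
    enet = list(num_comp = c(10, 150), lambda = c(1e-6, 1), alpha = c(0, 1)),
    rf = list(num_comp = c(20, 150), trees = c(500, 2000),
              mtry = c(5, 150), min_n = c(2, 20)),
    xgb = list(num_comp = c(15, 150), trees = c(500, 2500),
               learn_rate = c(10^-3.5, 0.1), depth = c(3, 8),
               min_n = c(2, 20), mtry = c(5, 150),
               subsample = c(0.5, 1), colsample = c(0.5, 1)),
    gpr = list(num_comp = c(10, 120), sigma = c(1e-3, 10))
  )
  for (fam in learner_families()) {
    cfgs <- hyperparam_space(fam, budget = 15, seed = 3)
    for (cf in cfgs) {
      for (p in names(cf)) {
        expect_gte(cf[[p]], bounds[[fam]][[p]][1])
        expect_lte(cf[[p]], bounds[[fam]][[p]][2])
      }
    }
    # determinism
    expect_identical(cfgs, hyperparam_space(fam, budget = 15, seed = 3))
  }
  # PLSR grid: integer components inside the printed range
  pls20 <- hyperparam_space("plsr", 20)
  ks <- vapply(pls20, `[[`, 0L, "num_comp")
  expect_length(ks, 20)
  expect_true(all(ks == as.integer(ks) & ks >= 2 & ks <= 120))
  # degenerate budget: space midpoint
  mid <- hyperparam_space("enet", 1)[[1]]
  expect_equal(mid$num_comp, 80)
  expect_equal(mid$alpha, 0.5)
  # k_max clips the component counts
  expect_true(all(vapply(hyperparam_space("pcr", 10, k_max = 12),
                         `[[`, 0L, "num_comp") <= 12))
  expect_error(hyperparam_space("nope", 5), "unknown")
})

test_that("one-SE selection returns the simplest near-optimal candidate", {
  mk <- function(mean, se, num_comp) {
    list(config = list(num_comp = num_comp), cv_rmse_mean = mean,
         cv_rmse_se = se)
  }
  # B is within one SE of A's minimum and simpler
  sel <- select_one_se(list(A = mk(2.00, 0.10, 50), B = mk(2.05, 0.10, 10),
                            C = mk(2.30, 0.10, 5)))
  expect_equal(sel$config$num_comp, 10)
  # single candidate: itself
  one <- mk(1, 0.1, 3)
  expect_identical(select_one_se(list(one)), one)
  # all means equal: pure simplicity tie-break
  sel2 <- select_one_se(list(mk(2, 0.1, 40), mk(2, 0.1, 4), mk(2, 0.1, 12)))
  expect_equal(sel2$config$num_comp, 4)
  expect_error(select_one_se(list()), "no candidates")
})

test_that("evaluation metrics match hand arithmetic", {
  ds <- craft_ds(dm = c(1, 2, 3))
  fake <- structure(list(pred = c(1, 2, 4)), class = "fake_model")
  assign("predict.fake_model", function(object, newdata, ...) object$pred,
         envir = globalenv())
  withr::defer(rm("predict.fake_model", envir = globalenv()))
  ev <- evaluate_learner(fake, ds)
  expect_equal(ev$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ev$r2, 0.5, tolerance = 1e-12)
  # constant prediction at the test mean: R^2 = 0 by definition
  fake$pred <- rep(2, 3)
  expect_equal(evaluate_learner(fake, ds)$r2, 0, tolerance = 1e-12)
})

test_that("PLSR drives CV error to zero on noise-free linear spectra", {
  ds <- generate_dataset(noisefree_config(n = 60, seed = 14))$dataset
  tn <- tune_learners(ds, families = "plsr", budgets = c(plsr = 4),
                      cv = cv_spec(folds = 3, repeats = 1, seed = 2))
  best <- tn$candidates$plsr[[1]]
  expect_lt(best$cv_rmse_mean, 1e-6)
})

test_that("every training sample is held out exactly once per repeat", {
  ds <- quick_ds(n = 40, seed = 23)
  tn <- tune_learners(ds, families = "pcr", budgets = c(pcr = 3),
                      cv = cv_spec(folds = 4, repeats = 2, seed = 6))
  for (cand in tn$candidates$pcr) {
    expect_false(anyNA(cand$oof))          # complete cover per repeat
    expect_equal(dim(cand$oof), c(40, 2))
  }
  # fold assignments partition the data per repeat
  for (f in tn$folds) expect_setequal(seq_len(4), unique(f))
})

test_that("PCR equals ordinary least squares on the leading scores", {
  tr <- quick_ds(n = 50, seed = 33)
  te <- quick_ds(n = 20, seed = 34)
  fl <- finalize_learner(tr, "pcr", list(num_comp = 3))
  p_pkg <- predict(fl, te)
  # oracle: base-R standardization, prcomp scores, lm
  mu <- colMeans(tr$refl); sdv <- apply(tr$refl, 2, sd)
  keep <- sdv > 0
  ztr <- scale(tr$refl[, keep], mu[keep], sdv[keep])
  pc <- prcomp(ztr, center = TRUE, scale. = FALSE)
  str_ <- pc$x[, 1:3]
  fit <- lm(tr$dm ~ str_)
  zte <- scale(te$refl[, keep], mu[keep], sdv[keep])
  ste <- scale(zte, pc$center, scale = FALSE) %*% pc$rotation[, 1:3]
  p_oracle <- cbind(1, ste) %*% coef(fit)
  expect_lt(max(abs(p_pkg - as.numeric(p_oracle))), 1e-8)
})

test_that("held-out fold predictions match a hand-rolled two-split oracle", {
  ds <- quick_ds(n = 12, seed = 41)
  tn <- tune_learners(ds, families = "pcr", budgets = c(pcr = 1),
                      cv = cv_spec(folds = 2, repeats = 1, seed = 9),
                      prep = prep_opts(variance_target = 0.5))
  cand <- tn$candidates$pcr[[1]]
  k <- cand$config$num_comp
  folds <- tn$folds[[1]]
  oracle <- rep(NA_real_, 12)
  for (f in 1:2) {
    tr <- which(folds != f); te <- which(folds == f)
    mu <- colMeans(ds$refl[tr, ]); sdv <- apply(ds$refl[tr, ], 2, sd)
    keep <- sdv > 0
    ztr <- scale(ds$refl[tr, keep], mu[keep], sdv[keep])
    pc <- prcomp(ztr)
    str_ <- pc$x[, 1:k, drop = FALSE]
    fit <- lm.fit(cbind(1, str_), ds$dm[tr])
    zte <- scale(ds$refl[te, keep], mu[keep], sdv[keep])
    ste <- scale(zte, pc$center, scale = FALSE) %*% pc$rotation[, 1:k, drop = FALSE]
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    oracle[te] <- cbind(1, ste) %*% cf
  }
  expect_lt(max(abs(cand$oof[, 1] - oracle)), 1e-8)
})

test_that("GPR posterior mean matches a closed-form kernel oracle", {
  set.seed(8)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- x[, 1] - 0.5 * x[, 2]^2 + rnorm(30, sd = 0.05)
  sigma <- 0.2
  fit <- specstack:::gpr_fit(x, y, sigma = sigma)
  p <- specstack:::gpr_predict(fit, x[1:5, , drop = FALSE])
  # oracle: dist()-based kernel on the same standardized inputs, qr solve
  xs <- scale(x)
  K <- exp(-sigma * as.matrix(dist(xs))^2)
  alpha <- qr.solve(K + diag(1e-6, 30), y - mean(y))
  p_oracle <- as.numeric(K[1:5, ] %*% alpha + mean(y))
  expect_lt(max(abs(p - p_oracle)), 1e-8)
  # interpolates training data closely at small jitter
  expect_lt(max(abs(specstack:::gpr_predict(fit, x) - y)), 1e-3)
})

test_that("null-mode spectra admit no cross-validated skill", {
  ds <- generate_dataset(synth_config(n = 100, seed = 55, mode = "null"))$dataset
  tn <- tune_learners(ds, families = c("pcr", "plsr"),
                      budgets = c(pcr = 3, plsr = 3),
                      cv = cv_spec(folds = 4, repeats = 1, seed = 3))
  sd_dm <- sd(ds$dm)
  for (fam in names(tn$candidates)) {
    for (cand in tn$candidates[[fam]]) {
      expect_gt(cand$cv_rmse_mean, 0.9 * sd_dm)
    }
  }
})

test_that("tree and boosted learners fit and predict on scores", {
  ds <- quick_ds(n = 60, seed = 66)
  te <- quick_ds(n = 25, seed = 67)
  for (fam in c("rf", "xgb", "enet", "gpr")) {
    cfg <- hyperparam_space(fam, 1, k_max = 10)[[1]]
    if (!is.null(cfg$trees)) cfg$trees <- 300
    fl <- finalize_learner(ds, fam, cfg, seed = 3)
    ev <- evaluate_learner(fl, te)
    expect_true(is.finite(ev$rmse))
    expect_gt(ev$r2, 0.3)   # default mechanism is learnable by every family
  }
})
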