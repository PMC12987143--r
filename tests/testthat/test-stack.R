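# Stacking engine: candidate library, OOF assembly, the non-negative LASSO
# meta-learner and the finalized ensemble.

test_that("meta-learner handles the exact-member and anti-correlated limits", {
  set.seed(1)
  y <- runif(30, 5, 40)
  # a candidate that already equals the target: full weight, zero intercept
  bl <- blend_nnlasso(cbind(m = y), y, lambda = 1e-6)
  expect_equal(unname(bl$weights), 1, tolerance = 1e-4)
  expect_equal(bl$intercept, 0, tolerance = 1e-3)
  # perfectly anti-correlated single column: non-negativity binds
  bl2 <- blend_nnlasso(cbind(m = -y), y, lambda = 1e-6)
  expect_equal(unname(bl2$weights), 0)
  expect_equal(bl2$intercept, mean(y), tolerance = 1e-8)
})

test_that("meta-learner matches the NNLS oracle on the printed toy problem", {
  y <- c(1, 2, 3, 4)
  O <- cbind(P1 = c(1.1, 1.9, 3.2, 3.8), P2 = c(0.9, 2.1, 2.8, 4.2))
  bl <- blend_nnlasso(O, y, lambda = 1e-6)
  or <- nnls_intercept_oracle(O, y)
  expect_lt(max(abs(unname(bl$weights) - or$weights)), 1e-4)
  expect_lt(abs(bl$intercept - or$intercept), 1e-4)
})

test_that("meta-learner matches the NNLS oracle across random problems", {
  for (s in 1:12) {
    set.seed(100 + s)
    n <- sample(20:80, 1); k <- sample(2:5, 1)
    y <- runif(n, 5, 40)
    O <- sapply(seq_len(k), function(j) y * runif(1, 0.6, 1.2) +
                  rnorm(n, sd = runif(1, 0.5, 3)))
    bl <- blend_nnlasso(O, y, lambda = 1e-6)
    or <- nnls_intercept_oracle(O, y)
    expect_lt(max(abs(unname(bl$weights) - or$weights)), 1e-4)
    # at lambda = 0 the solution is the NNLS-with-intercept optimum: same
    # weights to solver tolerance and the same fit to near machine precision
    bl0 <- blend_nnlasso(O, y, lambda = 0)
    expect_lt(max(abs(unname(bl0$weights) - or$weights)), 1e-4)
    expect_lt(abs(rmse(y, bl0$intercept + O %*% bl0$weights) -
                  rmse(y, or$intercept + O %*% or$weights)), 1e-8)
    # meta-fit dominance over every single column (with intercept)
    fit_rmse <- rmse(y, bl$intercept + O %*% bl$weights)
    single <- apply(O, 2, function(o) {
      f <- lm.fit(cbind(1, o), y)
      sqrt(mean(f$residuals^2))
    })
    expect_lte(fit_rmse, min(single) + 1e-6)
  }
})

test_that("large penalties shut every weight down", {
  set.seed(3)
  y <- runif(25, 5, 40)
  O <- cbind(y + rnorm(25), y + rnorm(25))
  bl <- blend_nnlasso(O, y, lambda = 1e6)
  expect_true(all(bl$weights == 0))
  expect_equal(bl$intercept, mean(y))
  expect_true(all(blend_nnlasso(O, y, lambda = 1e-6)$weights >= 0))
})

test_that("candidate library truncates per family without padding", {
  ds <- quick_ds(n = 40, seed = 71)
  tn <- tune_learners(ds, families = c("pcr", "gpr"),
                      budgets = c(pcr = 5, gpr = 4),
                      cv = cv_spec(folds = 3, repeats = 1, seed = 2))
  lib20 <- suppressWarnings(build_candidate_library(tn, top_m = 20))
  expect_lte(length(lib20), 2 * 20)
  skilled <- sum(vapply(c(tn$candidates$pcr, tn$candidates$gpr),
                        function(c) c$cv_rmse_mean < sqrt(0.9) * tn$train_dm_sd,
                        TRUE))
  expect_equal(length(lib20), skilled)
  # without the skill screen every tuned candidate is retained
  expect_equal(length(build_candidate_library(tn, 20, skill_screen = FALSE)),
               length(tn$candidates$pcr) + length(tn$candidates$gpr))
  lib1 <- build_candidate_library(tn, top_m = 1)
  expect_equal(vapply(lib1, `[[`, "", "id"), c("pcr_1", "gpr_1"))
  # mismatched resamples refuse to stack
  tn2 <- tune_learners(ds, families = "pcr", budgets = c(pcr = 2),
                       cv = cv_spec(folds = 3, repeats = 1, seed = 99))
  expect_error(build_candidate_library(list(tn, tn2), 5), "resamples")
})

test_that("OOF assembly averages repeats and rejects incomplete covers", {
  oof1 <- matrix(c(1, 2, 3, 3, 4, 5), 3, 2)   # two repeats
  cand <- list(list(id = "a_1", oof = oof1),
               list(id = "b_1", oof = oof1 * 0))
  M <- assemble_oof(cand)
  expect_equal(M[, "a_1"], c(2, 3, 4))
  expect_equal(M[, "b_1"], c(0, 0, 0))
  # averaging identical repeats is idempotent
  expect_equal(assemble_oof(list(list(id = "c", oof = cbind(1:3, 1:3))))[, 1],
               1:3)
  bad <- list(list(id = "a_1", oof = matrix(c(1, NA, 3), 3, 1)))
  expect_error(assemble_oof(bad), "missing")
})

test_that("weight report aggregates match an independent group sum", {
  ds <- quick_ds(n = 60, seed = 81)
  tn <- tune_learners(ds, families = c("pcr", "gpr"),
                      budgets = c(pcr = 4, gpr = 4),
                      cv = cv_spec(folds = 3, repeats = 1, seed = 4))
  st <- dm_stack(ds, tuning = tn, top_m = 3)
  wr <- report_weights(st)
  expect_true(all(wr$Weight >= 0))
  agg <- attr(wr, "family_weights")
  oracle <- tapply(wr$Weight, tolower(wr$Family), sum)
  expect_equal(sort(as.numeric(agg)), sort(as.numeric(oracle)), tolerance = 1e-12)
  # coef() exposes intercept plus member weights
  cf <- coef(st)
  expect_equal(unname(cf[1]), st$intercept)
  expect_true(all(cf[-1] > 0))
})

test_that("stack predictions are the weighted member combination", {
  ds <- quick_ds(n = 60, seed = 91)
  te <- quick_ds(n = 20, seed = 92)
  tn <- tune_learners(ds, families = c("pcr", "gpr"),
                      budgets = c(pcr = 3, gpr = 3),
                      cv = cv_spec(folds = 3, repeats = 1, seed = 5))
  st <- dm_stack(ds, tuning = tn, top_m = 2)
  p <- predict(st, te)
  manual <- rep(st$intercept, n_samples(te))
  for (i in seq_along(st$members)) {
    manual <- manual + st$weights[i] * predict(st$members[[i]], te)
  }
  expect_equal(p, unname(manual), tolerance = 1e-10)
  # meta-fit dominance on its own design matrix
  keep_cols <- names(st$weights)
  fit_rmse <- rmse(st$y_train,
                   st$intercept + st$oof[, keep_cols, drop = FALSE] %*% st$weights)
  single <- apply(st$oof, 2, function(o) {
    f <- lm.fit(cbind(1, o), st$y_train)
    sqrt(mean(f$residuals^2))
  })
  expect_lte(fit_rmse, min(single) + 1e-6)
})

test_that("the whole stack is reproducible under a fixed CV seed", {
  ds <- quick_ds(n = 50, seed = 101)
  run <- function() {
    tn <- tune_learners(ds, families = "pcr", budgets = c(pcr = 3),
                        cv = cv_spec(folds = 3, repeats = 1, seed = 11))
    dm_stack(ds, tuning = tn, top_m = 2)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$intercept, s2$intercept)
  te <- quick_ds(n = 10, seed = 102)
  expect_identical(predict(s1, te), predict(s2, te))
})
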