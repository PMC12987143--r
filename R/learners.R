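# Base-learner zoo: family registry, hyperparameter search spaces, repeated
# k-fold tuning with retained out-of-fold predictions, one-standard-error
# selection, finalization and test evaluation.
#
# All families except PLSR are trained on PCA scores of the standardized
# spectra; PLSR consumes the standardized full spectra (its own latent
# projection replaces PCA).

# ---- parameter bounds -------------------------------------------------------

.param_bounds <- list(
  pcr  = list(num_comp = list(10, 150, log = FALSE, int = TRUE)),
  plsr = list(num_comp = list(2, 120, log = FALSE, int = TRUE)),
  enet = list(num_comp = list(10, 150, log = FALSE, int = TRUE),
              lambda   = list(1e-6, 1, log = TRUE, int = FALSE),
              alpha    = list(0, 1, log = FALSE, int = FALSE)),
  rf   = list(num_comp = list(20, 150, log = FALSE, int = TRUE),
              trees    = list(500, 2000, log = FALSE, int = TRUE),
              mtry     = list(5, 150, log = FALSE, int = TRUE),
              min_n    = list(2, 20, log = FALSE, int = TRUE)),
  xgb  = list(num_comp = list(15, 150, log = FALSE, int = TRUE),
              trees    = list(500, 2500, log = FALSE, int = TRUE),
              learn_rate = list(10^-3.5, 10^-1, log = TRUE, int = FALSE),
              depth    = list(3, 8, log = FALSE, int = TRUE),
              min_n    = list(2, 20, log = FALSE, int = TRUE),
              mtry     = list(5, 150, log = FALSE, int = TRUE),
              subsample = list(0.5, 1, log = FALSE, int = FALSE),
              colsample = list(0.5, 1, log = FALSE, int = FALSE)),
  gpr  = list(num_comp = list(10, 120, log = FALSE, int = TRUE),
              sigma    = list(1e-3, 1e1, log = TRUE, int = FALSE))
)

#' Base-learner families
#'
#' @return Character vector of available family names: `"pcr"`, `"plsr"`,
#'   `"enet"`, `"rf"`, `"xgb"`, `"gpr"`.
#' @export
learner_families <- function() names(.param_bounds)

clip_num_comp <- function(cfgs, k_max) {
  lapply(cfgs, function(cf) {
    if (!is.null(cf$num_comp)) cf$num_comp <- max(1L, min(cf$num_comp, k_max))
    cf
  })
}

scale_param <- function(u, spec) {
  lo <- spec[[1]]; hi <- spec[[2]]
  v <- if (isTRUE(spec$log)) exp(log(lo) + u * (log(hi) - log(lo)))
       else lo + u * (hi - lo)
  if (isTRUE(spec$int)) as.integer(round(v)) else v
}

#' Sample a hyperparameter search space
#'
#' Families tuned only on the number of components get an evenly spaced
#' integer grid; multi-parameter families get a seeded Latin-hypercube sample
#' within the documented bounds (log-scaled where the bounds are log-scaled).
#' `budget = 1` returns the space midpoint. GPR uses a two-stage scheme
#' handled by [tune_learners()]: this function returns its stage-1 grid
#' (components swept with the kernel bandwidth held at the log-midpoint).
#'
#' @param family Family name (see [learner_families()]).
#' @param budget Number of configurations (>= 1).
#' @param seed Integer seed.
#' @param k_max Upper bound for `num_comp` (e.g. the PCA rank retained).
#' @return List of named configuration lists.
#' @export
hyperparam_space <- function(family, budget, seed = 1, k_max = Inf) {
  bounds <- .param_bounds[[family]]
  if (is.null(bounds)) stopf("unknown learner family '%s'", family)
  if (budget < 1L) stopf("`budget` must be >= 1")
  pnames <- names(bounds)
  if (identical(pnames, "num_comp")) {
    lo <- bounds$num_comp[[1]]; hi <- min(bounds$num_comp[[2]], k_max)
    if (hi < lo) hi <- lo <- min(lo, k_max)
    vals <- if (budget == 1L) as.integer(round((lo + hi) / 2)) else
      unique(as.integer(round(seq(lo, hi, length.out = budget))))
    return(lapply(vals, function(v) list(num_comp = v)))
  }
  if (family == "gpr") {
    b1 <- max(1L, ceiling(budget / 2))
    lo <- bounds$num_comp[[1]]; hi <- min(bounds$num_comp[[2]], k_max)
    if (hi < lo) hi <- lo <- min(lo, k_max)
    ks <- if (b1 == 1L) as.integer(round((lo + hi) / 2)) else
      unique(as.integer(round(seq(lo, hi, length.out = b1))))
    sig_mid <- exp(mean(log(c(bounds$sigma[[1]], bounds$sigma[[2]]))))
    cfgs <- lapply(ks, function(k) list(num_comp = k, sigma = sig_mid))
    attr(cfgs, "stage2_budget") <- budget - length(cfgs)
    return(cfgs)
  }
  U <- if (budget == 1L) matrix(0.5, 1L, length(pnames)) else
    with_seed(seed, lhs::randomLHS(budget, length(pnames)))
  cfgs <- lapply(seq_len(budget), function(i) {
    cf <- stats::setNames(
      lapply(seq_along(pnames), function(j) scale_param(U[i, j], bounds[[j]])),
      pnames)
    cf
  })
  clip_num_comp(cfgs, k_max)
}

gpr_stage2_space <- function(best_num_comp, budget) {
  if (budget < 1L) return(list())
  bounds <- .param_bounds$gpr$sigma
  sig <- if (budget == 1L) exp(mean(log(c(bounds[[1]], bounds[[2]])))) else
    exp(seq(log(bounds[[1]]), log(bounds[[2]]), length.out = budget))
  lapply(sig, function(s) list(num_comp = best_num_comp, sigma = s))
}

# ---- individual learners ----------------------------------------------------

fit_learner <- function(family, x, y, config, seed = 1) {
  switch(family,
    pcr = {
      k <- config$num_comp
      xs <- x[, seq_len(min(k, ncol(x))), drop = FALSE]
      fit <- stats::lm.fit(cbind(1, xs), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0   # aliased (rank-deficient) scores contribute nothing
      list(kind = "pcr", coef = cf, k = ncol(xs))
    },
    plsr = {
      k <- min(config$num_comp, ncol(x) - 1L, nrow(x) - 1L)
      xm <- as.matrix(x)   # standardized spectra (train-only statistics)
      if (is.null(colnames(xm))) colnames(xm) <- paste0("V", seq_len(ncol(xm)))
      fit <- mixOmics::pls(xm, y, ncomp = k, mode = "regression", scale = FALSE)
      list(kind = "plsr", fit = fit, k = k)
    },
    enet = {
      k <- min(config$num_comp, ncol(x))
      xs <- x[, seq_len(k), drop = FALSE]
      fit <- glmnet::glmnet(xs, y, alpha = config$alpha, standardize = TRUE)
      list(kind = "enet", fit = fit, k = k, lambda = config$lambda)
    },
    rf = {
      k <- min(config$num_comp, ncol(x))
      xs <- as.data.frame(x[, seq_len(k), drop = FALSE])
      names(xs) <- paste0("PC", seq_len(k))
      fit <- ranger::ranger(y = y, x = xs, num.trees = config$trees,
                            mtry = min(config$mtry, k),
                            min.node.size = config$min_n,
                            seed = seed, num.threads = 1)
      list(kind = "rf", fit = fit, k = k)
    },
    xgb = {
      k <- min(config$num_comp, ncol(x))
      xs <- x[, seq_len(k), drop = FALSE]
      d <- xgboost::xgb.DMatrix(xs, label = y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(eta = config$learn_rate, max_depth = config$depth,
                      min_child_weight = config$min_n,
                      subsample = config$subsample,
                      colsample_bytree = min(1, config$mtry / k),
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = d, nrounds = config$trees, verbose = 0)
      list(kind = "xgb", fit = fit, k = k)
    },
    gpr = {
      k <- min(config$num_comp, ncol(x))
      xs <- x[, seq_len(k), drop = FALSE]
      fit <- gpr_fit(xs, y, sigma = config$sigma)
      list(kind = "gpr", fit = fit, k = k)
    },
    stopf("unknown learner family '%s'", family)
  )
}

predict_learner <- function(model, x) {
  k <- model$k
  switch(model$kind,
    pcr = {
      xs <- x[, seq_len(k), drop = FALSE]
      as.numeric(model$coef[1] + xs %*% model$coef[-1])
    },
    plsr = {
      xm <- as.matrix(x)
      colnames(xm) <- colnames(model$fit$X)
      pr <- predict(model$fit, xm)$predict
      as.numeric(pr[, 1, k])
    },
    enet = as.numeric(predict(model$fit, x[, seq_len(k), drop = FALSE],
                              s = model$lambda)),
    rf = {
      xs <- as.data.frame(x[, seq_len(k), drop = FALSE])
      names(xs) <- paste0("PC", seq_len(k))
      predict(model$fit, xs, num.threads = 1)$predictions
    },
    xgb = as.numeric(predict(model$fit,
                             xgboost::xgb.DMatrix(x[, seq_len(k), drop = FALSE],
                                                  nthread = 1))),
    gpr = gpr_predict(model$fit, x[, seq_len(k), drop = FALSE])
  )
}

# Gaussian process regression posterior mean, radial-basis kernel
# k(x, x') = exp(-sigma * ||x - x'||^2) (inverse-width convention), inputs
# standardized internally, fixed diagonal jitter for numerical stability.
gpr_fit <- function(x, y, sigma, jitter = 1e-6) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  ymean <- mean(y)
  K <- exp(-sigma * sq_dists(xs, xs))
  alpha <- solve(K + diag(jitter, nrow(K)), y - ymean)
  list(xs = xs, mu = mu, sdv = sdv, sigma = sigma, alpha = alpha, ymean = ymean)
}

gpr_predict <- function(fit, xnew) {
  xs <- scale(as.matrix(xnew), fit$mu, fit$sdv)
  Ks <- exp(-fit$sigma * sq_dists(xs, fit$xs))
  as.numeric(Ks %*% fit$alpha + fit$ymean)
}

sq_dists <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

# ---- cross-validation -------------------------------------------------------

#' Repeated k-fold cross-validation specification
#'
#' @param folds Number of folds (>= 2); the modeling default is 10.
#' @param repeats Number of repeats (>= 1); default 3.
#' @param seed Integer seed controlling the fold assignments.
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(folds = 10, repeats = 3, seed = 1) {
  if (folds < 2L) stopf("`folds` must be >= 2")
  if (repeats < 1L) stopf("`repeats` must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = seed), class = "cv_spec")
}

make_folds <- function(n, cv) {
  lapply(seq_len(cv$repeats), function(r)
    with_seed(cv$seed + 7919 * r, sample(rep_len(seq_len(cv$folds), n))))
}

# Per-(repeat, fold) preprocessed views of the training data.
build_fold_data <- function(train, cv, prep) {
  folds <- make_folds(n_samples(train), cv)
  shared <- if (prep$pca_refit == "train") fit_preprocess(train, prep) else NULL
  fold_data <- list()
  for (r in seq_len(cv$repeats)) {
    for (f in seq_len(cv$folds)) {
      te <- which(folds[[r]] == f)
      tr <- setdiff(seq_len(n_samples(train)), te)
      pm <- if (is.null(shared)) fit_preprocess(train[tr], prep) else shared
      fold_data[[length(fold_data) + 1L]] <- list(
        rep = r, fold = f, tr = tr, te = te, prep = pm,
        scores_tr = transform_spectra(pm, train[tr]),
        scores_te = transform_spectra(pm, train[te]),
        k_max = pm$pca$k_max)
    }
  }
  list(folds = folds, fold_data = fold_data,
       k_max = min(vapply(fold_data, `[[`, 0L, "k_max")))
}

# PLSR consumes the standardized full spectra (its own latent projection
# replaces PCA); zero-variance bands are dropped by the fold standardizer.
plsr_input <- function(prep_model, x) {
  transform_spectra(prep_model, x, output = "standardized")
}

evaluate_family_configs <- function(family, configs, train, fd, cv, prep) {
  n <- n_samples(train)
  ncf <- length(configs)
  if (!ncf) return(list())
  oof <- lapply(seq_len(ncf), function(i) matrix(NA_real_, n, cv$repeats))
  frmse <- lapply(seq_len(ncf), function(i) matrix(NA_real_, cv$repeats, cv$folds))
  failed <- logical(ncf)
  for (fdx in fd$fold_data) {
    y_tr <- train$dm[fdx$tr]; y_te <- train$dm[fdx$te]
    if (family == "plsr") {
      x_tr <- plsr_input(fdx$prep, train[fdx$tr])
      x_te <- plsr_input(fdx$prep, train[fdx$te])
      # One fit at the largest feasible component count serves every
      # configuration (held-out predictions are extracted per dimension).
      # Beyond the effective rank of the standardized fold data the latent
      # projection carries no information (and eventually degenerates
      # numerically), so component counts are capped at that rank — the PCA
      # of the identical fold matrix has already measured it.
      rank_std <- length(fdx$prep$pca$eigenvalues)
      ks <- sort(unique(pmin(vapply(configs, `[[`, 0L, "num_comp"), rank_std)),
                 decreasing = TRUE)
      model <- NULL; pr <- NULL
      for (k_try in ks) {
        done <- tryCatch({
          model <- fit_learner("plsr", x_tr, y_tr,
                               list(num_comp = k_try), seed = cv$seed)
          xm <- as.matrix(x_te); colnames(xm) <- colnames(model$fit$X)
          pr <- predict(model$fit, xm)$predict  # n_te x 1 x ncomp
          TRUE
        }, error = function(e) FALSE)
        if (done) break
      }
      if (is.null(pr)) {
        warnf("plsr failed at every component count in fold (%d,%d)",
              fdx$rep, fdx$fold)
      }
      for (i in seq_len(ncf)) {
        k <- min(configs[[i]]$num_comp, rank_std)
        if (is.null(pr) || k > model$k) { failed[i] <- TRUE; next }
        p <- as.numeric(pr[, 1, k])
        oof[[i]][fdx$te, fdx$rep] <- p
        frmse[[i]][fdx$rep, fdx$fold] <- rmse(y_te, p)
      }
    } else {
      for (i in seq_len(ncf)) {
        p <- tryCatch({
          m <- fit_learner(family, fdx$scores_tr, y_tr, configs[[i]],
                           seed = cv$seed + 131 * i)
          predict_learner(m, fdx$scores_te)
        }, error = function(e) {
          warnf("%s config %d failed in fold (%d,%d): %s", family, i,
                fdx$rep, fdx$fold, conditionMessage(e))
          NULL
        })
        if (is.null(p)) { failed[i] <- TRUE; next }
        oof[[i]][fdx$te, fdx$rep] <- p
        frmse[[i]][fdx$rep, fdx$fold] <- rmse(y_te, p)
      }
    }
  }
  lapply(seq_len(ncf), function(i) {
    fr <- frmse[[i]]
    list(family = family, config = configs[[i]],
         cv_rmse_mean = mean(fr, na.rm = TRUE),
         cv_rmse_se = stats::sd(as.vector(fr), na.rm = TRUE) /
           sqrt(sum(is.finite(fr))),
         fold_rmse = fr, oof = oof[[i]], failed = failed[i])
  })
}

#' Tune base learners by repeated k-fold cross-validation
#'
#' For every family, samples its hyperparameter space, evaluates each
#' configuration on a shared set of resamples (identical folds across all
#' families and configurations, which licenses candidate-level stacking on
#' the out-of-fold predictions), and ranks configurations by mean held-out
#' RMSE. Preprocessing (standardizer + PCA) is refit inside every training
#' fold by default so no held-out statistics leak into fitting.
#'
#' @param train Training [spectra_dataset()].
#' @param families Character vector of family names (see
#'   [learner_families()]).
#' @param budgets Named integer vector (or single integer) of configurations
#'   per family.
#' @param cv A [cv_spec()].
#' @param prep A [prep_opts()].
#' @return A `tuning_result`: list with `candidates` (per family, sorted by
#'   CV RMSE, each carrying config, CV metrics and the n x repeats out-of-fold
#'   prediction matrix), `cv`, `prep`, `folds`, `k_max`, `train_ids`.
#' @export
tune_learners <- function(train,
                          families = c("plsr", "pcr", "enet", "gpr", "rf", "xgb"),
                          budgets = c(pcr = 20, plsr = 20, enet = 30,
                                      gpr = 20, rf = 60, xgb = 60),
                          cv = cv_spec(), prep = prep_opts()) {
  stopifnot(inherits(train, "spectra_dataset"))
  unknown <- setdiff(families, learner_families())
  if (length(unknown)) stopf("unknown families: %s", paste(unknown, collapse = ", "))
  if (n_samples(train) < cv$folds) stopf("fewer training samples than folds")
  if (length(budgets) == 1L && is.null(names(budgets))) {
    budgets <- stats::setNames(rep(budgets, length(families)), families)
  }
  fd <- build_fold_data(train, cv, prep)
  candidates <- list()
  for (fam in families) {
    b <- budgets[[fam]]
    if (is.null(b)) b <- 20L
    # PLSR works on the standardized full spectra, so its component bound is
    # the data rank, not the PCA rank retained for the other families.
    fam_k_max <- if (fam == "plsr") {
      min(n_samples(train) - 1L, length(train$wl))
    } else {
      fd$k_max
    }
    cfgs <- hyperparam_space(fam, b, seed = cv$seed + config_hash(fam) %% 10000,
                             k_max = fam_k_max)
    res <- evaluate_family_configs(fam, cfgs, train, fd, cv, prep)
    if (fam == "gpr") {
      b2 <- attr(cfgs, "stage2_budget")
      ok <- !vapply(res, `[[`, TRUE, "failed")
      if (b2 > 0 && any(ok)) {
        best_k <- res[[which.min(vapply(res, function(r)
          ifelse(r$failed, Inf, r$cv_rmse_mean), 0))]]$config$num_comp
        cfg2 <- gpr_stage2_space(best_k, b2)
        res <- c(res, evaluate_family_configs(fam, cfg2, train, fd, cv, prep))
      }
    }
    res <- Filter(function(r) !r$failed && is.finite(r$cv_rmse_mean), res)
    if (!length(res)) { warnf("family %s: no successful candidates", fam); next }
    ord <- order(vapply(res, `[[`, 0, "cv_rmse_mean"))
    res <- res[ord]
    for (i in seq_along(res)) {
      res[[i]]$id <- paste0(fam, "_", i)
      res[[i]]$rank <- i
    }
    candidates[[fam]] <- res
  }
  structure(list(candidates = candidates, cv = cv, prep = prep,
                 folds = fd$folds, k_max = fd$k_max, train_ids = train$ids,
                 train_dm_sd = stats::sd(train$dm)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d folds x %d repeats, k_max = %d\n",
              x$cv$folds, x$cv$repeats, x$k_max))
  for (fam in names(x$candidates)) {
    best <- x$candidates[[fam]][[1]]
    cat(sprintf("  %-5s %3d candidates; best CV RMSE %.3f +/- %.3f\n",
                fam, length(x$candidates[[fam]]), best$cv_rmse_mean, best$cv_rmse_se))
  }
  invisible(x)
}

# ---- one-standard-error selection ------------------------------------------

# Simplicity key, lexicographic ascending = simpler: fewer components, then
# shallower depth, then fewer trees, then larger min_n, then smaller mtry,
# then larger penalty.
simplicity_key <- function(config) {
  g <- function(nm, sgn = 1, default = 0) {
    v <- config[[nm]]
    if (is.null(v)) default else sgn * v
  }
  c(g("num_comp"), g("depth"), g("trees"), g("min_n", -1), g("mtry"),
    if (is.null(config$lambda)) 0 else -log10(config$lambda))
}

#' One-standard-error candidate selection
#'
#' Among candidates whose mean CV RMSE is within one standard error of the
#' minimum, returns the simplest configuration (fewest components, then
#' shallowest trees, fewest trees, largest terminal nodes, smallest mtry,
#' largest penalty); ties break on lower CV RMSE and finally on a
#' deterministic configuration hash.
#'
#' @param candidates List of candidate records (e.g. one family's entry of a
#'   `tuning_result`).
#' @return The selected candidate record.
#' @export
select_one_se <- function(candidates) {
  if (!length(candidates)) stopf("no candidates to select from")
  means <- vapply(candidates, `[[`, 0, "cv_rmse_mean")
  best <- which.min(means)
  thr <- means[best] + candidates[[best]]$cv_rmse_se
  elig <- which(means <= thr)
  keys <- lapply(candidates[elig], function(c) simplicity_key(c$config))
  ordmat <- do.call(rbind, keys)
  o <- do.call(order, c(as.data.frame(ordmat),
                        list(means[elig],
                             vapply(candidates[elig], function(c)
                               config_hash(c$config), 0))))
  candidates[[elig[o[1]]]]
}

# ---- finalization and evaluation -------------------------------------------

#' Finalize a tuned candidate on the full training set
#'
#' Refits preprocessing and the learner on all training samples.
#'
#' @param train Training [spectra_dataset()].
#' @param family Family name.
#' @param config Hyperparameter configuration list.
#' @param prep A [prep_opts()] or an already fitted `prep_model` (shared
#'   across stack members).
#' @param seed Integer seed for stochastic learners.
#' @return A `fitted_learner`.
#' @export
finalize_learner <- function(train, family, config, prep = prep_opts(), seed = 1) {
  pm <- if (inherits(prep, "prep_model")) prep else fit_preprocess(train, prep)
  x <- if (family == "plsr") plsr_input(pm, train)
       else transform_spectra(pm, train)
  model <- fit_learner(family, x, train$dm, config, seed = seed)
  structure(list(family = family, config = config, prep = pm, model = model),
            class = "fitted_learner")
}

#' Predict from a finalized learner
#' @param object A `fitted_learner`.
#' @param newdata A [spectra_dataset()] or reflectance matrix.
#' @param ... Ignored.
#' @return Numeric vector of predicted dry matter (%).
#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  x <- if (object$family == "plsr") plsr_input(object$prep, newdata)
       else transform_spectra(object$prep, newdata)
  predict_learner(object$model, x)
}

#' Evaluate predictions on a held-out test set
#'
#' @param fitted A `fitted_learner` (or any object with a `predict` method
#'   returning DM %).
#' @param test Test [spectra_dataset()] with n >= 2.
#' @return List with `rmse` (DM %) and `r2`.
#' @export
evaluate_learner <- function(fitted, test) {
  if (n_samples(test) < 2L) stopf("test set needs n >= 2")
  p <- predict(fitted, test)
  list(rmse = rmse(test$dm, p), r2 = rsq(test$dm, p))
}

#' Single-model benchmark table
#'
#' For each tuned family: one-SE selection, full-train refit, test
#' evaluation.
#'
#' @param tuning A `tuning_result`.
#' @param train,test [spectra_dataset()]s.
#' @return Data frame (family, id, num_comp, cv_rmse, test_rmse, test_r2)
#'   sorted by decreasing test R^2.
#' @export
single_model_benchmark <- function(tuning, train, test) {
  rows <- lapply(names(tuning$candidates), function(fam) {
    sel <- select_one_se(tuning$candidates[[fam]])
    fl <- finalize_learner(train, fam, sel$config, tuning$prep, seed = tuning$cv$seed)
    ev <- evaluate_learner(fl, test)
    data.frame(family = fam, id = sel$id,
               num_comp = ifelse(is.null(sel$config$num_comp), NA,
                                 sel$config$num_comp),
               cv_rmse = sel$cv_rmse_mean,
               test_rmse = ev$rmse, test_r2 = ev$r2)
  })
  out <- do.call(rbind, rows)
  out[order(-out$test_r2), , drop = FALSE]
}
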