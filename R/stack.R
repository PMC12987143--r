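# Candidate-level stacking: candidate library, out-of-fold design matrix,
# non-negative LASSO meta-learner, finalized ensemble and its S3 methods.

#' Build the candidate library for stacking
#'
#' Takes the top `top_m` configurations per family (by mean CV RMSE) from one
#' tuning run, or from several runs that used identical resamples. Candidate
#' ids follow the `family_rank` convention (e.g. `"gpr_4"`).
#'
#' Candidates without minimal cross-validated skill — CV R^2 below 0.1,
#' i.e. mean CV RMSE above `sqrt(0.9)` times the training trait's standard
#' deviation — are screened out (unless no candidate qualifies, in which
#' case all are kept). Such candidates are within sampling noise of the
#' trivial mean predictor: their out-of-fold columns are nearly constant and
#' enter the meta-fit only through degeneracy with the intercept, while
#' behaving entirely differently once refit on the full training set.
#'
#' @param tuning A `tuning_result`, or a list of them fitted with the same
#'   [cv_spec()] (identical folds); mismatched resamples are a hard error
#'   since stacking across different folds would leak.
#' @param top_m Configurations retained per family (default 20).
#' @param skill_screen Apply the no-skill screen (default `TRUE`).
#' @return List of candidate records.
#' @export
build_candidate_library <- function(tuning, top_m = 20, skill_screen = TRUE) {
  if (top_m < 1L) stopf("`top_m` must be >= 1")
  tunings <- if (inherits(tuning, "tuning_result")) list(tuning) else tuning
  ref <- tunings[[1]]
  for (t in tunings[-1]) {
    if (!identical(t$folds, ref$folds) || !identical(t$train_ids, ref$train_ids)) {
      stopf("candidates were tuned on different resamples; refuse to stack")
    }
  }
  lib <- list()
  for (t in tunings) {
    for (fam in names(t$candidates)) {
      cands <- t$candidates[[fam]]
      lib <- c(lib, cands[seq_len(min(top_m, length(cands)))])
    }
  }
  if (!length(lib)) stopf("empty candidate library")
  if (skill_screen && !is.null(ref$train_dm_sd)) {
    thr <- sqrt(0.9) * ref$train_dm_sd   # CV R^2 >= 0.1
    skilled <- vapply(lib, function(c) c$cv_rmse_mean < thr, TRUE)
    if (any(skilled) && !all(skilled)) {
      warnf("excluding %d no-skill candidate(s) from the meta design: %s",
            sum(!skilled),
            paste(vapply(lib[!skilled], `[[`, "", "id"), collapse = ", "))
      lib <- lib[skilled]
    }
  }
  lib
}

#' Assemble the out-of-fold prediction matrix
#'
#' Cell (i, c) is candidate c's held-out prediction for training sample i,
#' averaged over the cross-validation repeats. Every sample is predicted
#' exactly once per repeat, so the matrix is complete by construction.
#'
#' @param library Candidate list from [build_candidate_library()].
#' @param train_ids Training sample ids (row names).
#' @return Numeric matrix, n_train x n_candidates.
#' @export
assemble_oof <- function(library, train_ids = NULL) {
  cols <- lapply(library, function(c) rowMeans(c$oof))
  oof <- do.call(cbind, cols)
  colnames(oof) <- vapply(library, `[[`, "", "id")
  if (!is.null(train_ids)) rownames(oof) <- train_ids
  if (anyNA(oof)) stopf("out-of-fold matrix has missing cells; fold cover violated")
  oof
}

#' Non-negative LASSO meta-learner
#'
#' Solves `min_{w >= 0, b} (1/2n) * sum_i (y_i - b - sum_c w_c o_ic)^2 +
#' lambda * sum_c w_c` by cyclic coordinate descent with non-negativity
#' clipping; the intercept is unpenalized. Deterministic: coordinates are
#' visited in column order.
#'
#' @param oof Out-of-fold prediction matrix (n x candidates).
#' @param y Observed dry matter (%) for the n training samples.
#' @param lambda L1 penalty; the ensemble default is a near-vanishing 1e-6,
#'   so the fit is essentially non-negative least squares with sparsity
#'   resolved deterministically.
#' @param tol Convergence threshold on the largest coefficient change per
#'   sweep (default 1e-8).
#' @param max_iter Maximum sweeps (default 1e5).
#' @details Out-of-fold columns of strong candidates are often nearly
#'   collinear, which makes pure coordinate descent crawl along a flat
#'   valley. Once sweeps stop making progress, the solver therefore refines
#'   the solution by exact penalized least squares on the current active set,
#'   verifying the Karush-Kuhn-Tucker conditions of the full problem before
#'   declaring convergence. Exactly duplicated columns (a singular active
#'   set) retain the coordinate-descent solution, whose tie-break is the
#'   deterministic coordinate order.
#' @return List with `weights` (named, all >= 0), `intercept`, `iterations`,
#'   `converged`.
#' @export
blend_nnlasso <- function(oof, y, lambda = 1e-6, tol = 1e-8, max_iter = 1e5) {
  O <- as.matrix(oof)
  n <- nrow(O)
  if (length(y) != n) stopf("length(y) != nrow(oof)")
  if (lambda < 0) stopf("`lambda` must be >= 0")
  C <- ncol(O)
  w <- numeric(C)
  b <- mean(y)
  cn <- colSums(O^2) / n
  r <- y - b                      # residual y - b - O w  (w = 0)
  iter <- 0L
  obj_prev <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- 0
    for (j in seq_len(C)) {
      if (cn[j] == 0) next
      rho <- sum(O[, j] * r) / n + cn[j] * w[j]
      wj <- max(0, (rho - lambda) / cn[j])
      if (wj != w[j]) {
        r <- r - O[, j] * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    db <- mean(r)
    if (db != 0) {
      b <- b + db
      r <- r - db
      delta <- max(delta, abs(db))
    }
    obj <- 0.5 * mean(r^2) + lambda * sum(w)
    # leave the sweeping phase once steps are tiny or progress has flattened
    if (delta < tol || obj_prev - obj < 1e-10 * (1 + abs(obj))) break
    obj_prev <- obj
  }

  # Active-set refinement: exact penalized least squares on the active set,
  # then KKT verification on the full problem.
  converged <- FALSE
  singular <- FALSE
  active <- which(w > 0)
  for (t in seq_len(10L * (C + 1L))) {
    repeat {
      if (!length(active)) { w[] <- 0; b <- mean(y); break }
      Xa <- O[, active, drop = FALSE]
      A <- rbind(cbind(crossprod(Xa) / n, colMeans(Xa)),
                 c(colMeans(Xa), 1))
      rhs <- c(crossprod(Xa, y) / n - lambda, mean(y))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) { singular <- TRUE; break }
      wa <- sol[seq_along(active)]
      if (all(wa > -1e-12)) {
        w[] <- 0
        w[active] <- pmax(wa, 0)
        b <- unname(sol[length(sol)])
        break
      }
      active <- setdiff(active, active[which.min(wa)])
    }
    if (singular) { converged <- TRUE; break }   # duplicates: keep CD solution
    r <- as.numeric(y - b - O %*% w)
    grad <- -as.numeric(crossprod(O, r)) / n + lambda
    viol <- which(w == 0 & grad < -1e-10 & cn > 0)
    if (!length(viol)) { converged <- TRUE; break }
    active <- sort(c(active, viol[which.min(grad[viol])]))
  }
  if (!converged) {
    stopf("meta-learner did not converge (n = %d, %d candidates, lambda = %g)",
          n, C, lambda)
  }
  list(weights = stats::setNames(w, colnames(O)), intercept = unname(b),
       iterations = iter, converged = converged)
}

#' Fit a stacked dry matter ensemble
#'
#' The package's central fitting function. Tunes the requested base-learner
#' families by repeated k-fold cross-validation, assembles the out-of-fold
#' prediction matrix of the top `top_m` candidates per family, blends the
#' candidates with a non-negative LASSO meta-learner (fixed penalty
#' `lambda`), and refits the retained members on the full training set.
#'
#' @param train Training [spectra_dataset()].
#' @param families Base-learner families (see [learner_families()]).
#' @param budgets Configurations per family, as in [tune_learners()].
#' @param cv A [cv_spec()].
#' @param prep A [prep_opts()].
#' @param top_m Candidates retained per family for the meta-learner.
#' @param lambda Meta-learner L1 penalty (default 1e-6).
#' @param tuning Optionally, a precomputed `tuning_result` for `train`
#'   (skips tuning).
#' @return An object of class `dm_stack` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @export
dm_stack <- function(train,
                     families = c("plsr", "pcr", "enet", "gpr", "rf", "xgb"),
                     budgets = c(pcr = 20, plsr = 20, enet = 30,
                                 gpr = 20, rf = 60, xgb = 60),
                     cv = cv_spec(), prep = prep_opts(),
                     top_m = 20, lambda = 1e-6, tuning = NULL) {
  stopifnot(inherits(train, "spectra_dataset"))
  if (is.null(tuning)) {
    tuning <- tune_learners(train, families, budgets, cv, prep)
  }
  lib <- build_candidate_library(tuning, top_m)
  oof <- assemble_oof(lib, tuning$train_ids)
  bl <- blend_nnlasso(oof, train$dm, lambda = lambda)
  keep <- which(bl$weights > 0)
  if (!length(keep)) stopf("meta-learner retained no members")
  pm <- fit_preprocess(train, tuning$prep)
  members <- lapply(lib[keep], function(c)
    finalize_learner(train, c$family, c$config, pm, seed = tuning$cv$seed))
  meta <- do.call(rbind, lapply(lib, function(c) {
    cf <- c$config
    data.frame(id = c$id, family = c$family, rank = c$rank,
               cv_rmse = c$cv_rmse_mean, cv_se = c$cv_rmse_se,
               num_comp = cf$num_comp %||% NA,
               sigma = cf$sigma %||% NA, trees = cf$trees %||% NA,
               depth = cf$depth %||% NA, learn_rate = cf$learn_rate %||% NA,
               mtry = cf$mtry %||% NA, min_n = cf$min_n %||% NA,
               lambda = cf$lambda %||% NA, alpha = cf$alpha %||% NA,
               weight = unname(bl$weights[c$id]))
  }))
  obj <- structure(list(
    weights = bl$weights[keep], intercept = bl$intercept,
    members = members, candidates = meta, oof = oof, y_train = train$dm,
    prep = pm, cv = tuning$cv, lambda = lambda, top_m = top_m,
    meta_iterations = bl$iterations, tuning = tuning
  ), class = "dm_stack")
  p_tr <- predict(obj, train)
  obj$train_rmse <- rmse(train$dm, p_tr)
  obj$train_r2 <- rsq(train$dm, p_tr)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict dry matter from a stacked ensemble
#'
#' @param object A `dm_stack`.
#' @param newdata A [spectra_dataset()] or reflectance matrix on the model's
#'   grid.
#' @param ... Ignored.
#' @return Numeric vector of predicted dry matter (%).
#' @export
predict.dm_stack <- function(object, newdata, ...) {
  refl <- as_refl_matrix(newdata)
  # transform once, reuse across members sharing the preprocessing model
  fams <- vapply(object$members, `[[`, "", "family")
  scores <- if (any(fams != "plsr")) transform_spectra(object$prep, refl) else NULL
  std <- if (any(fams == "plsr")) plsr_input(object$prep, refl) else NULL
  p <- rep(object$intercept, nrow(refl))
  for (i in seq_along(object$members)) {
    x <- if (fams[i] == "plsr") std else scores
    p <- p + object$weights[i] * predict_learner(object$members[[i]]$model, x)
  }
  unname(p)
}

#' Member and family weight report
#'
#' @param model A `dm_stack`.
#' @return A `weight_report` data frame: one row per retained member
#'   (Family, Model, Weight, hyperparameters), with the per-family aggregated
#'   weights as attribute `family_weights`.
#' @export
report_weights <- function(model) {
  stopifnot(inherits(model, "dm_stack"))
  meta <- model$candidates
  rows <- meta[meta$weight > 0, , drop = FALSE]
  rows <- rows[order(-rows$weight), , drop = FALSE]
  out <- data.frame(Family = toupper(rows$family), Model = rows$id,
                    Weight = rows$weight, K = rows$num_comp,
                    sigma = rows$sigma, Trees = rows$trees,
                    Depth = rows$depth, LR = rows$learn_rate,
                    mtry = rows$mtry, min_n = rows$min_n)
  fam_w <- tapply(rows$weight, rows$family, sum)
  structure(out, class = c("weight_report", "data.frame"),
            family_weights = sort(unlist(as.list(fam_w)), decreasing = TRUE),
            intercept = model$intercept)
}

#' @export
print.weight_report <- function(x, ...) {
  cat(sprintf("Retained base learners (%d members, intercept %.3f):\n",
              nrow(x), attr(x, "intercept")))
  print.data.frame(cbind(x[1:3], round(x[-(1:3)], 4)), row.names = FALSE)
  cat("\nFamily aggregate weights:\n")
  print(round(attr(x, "family_weights"), 4))
  invisible(x)
}

#' @export
print.dm_stack <- function(x, ...) {
  cat(sprintf("<dm_stack> %d members from %d candidates (top %d per family)\n",
              length(x$members), nrow(x$candidates), x$top_m))
  cat(sprintf("  meta-learner: non-negative LASSO, lambda = %g, intercept = %.3f\n",
              x$lambda, x$intercept))
  cat(sprintf("  training fit: RMSE %.3f%%, R2 %.3f\n", x$train_rmse, x$train_r2))
  invisible(x)
}

#' @export
summary.dm_stack <- function(object, ...) {
  print(object)
  cat("\n")
  print(report_weights(object))
  invisible(object)
}

#' @export
coef.dm_stack <- function(object, ...) {
  c("(Intercept)" = unname(object$intercept), object$weights)
}

#' @export
plot.dm_stack <- function(x, ...) {
  fw <- attr(report_weights(x), "family_weights")
  graphics::barplot(fw, ylab = "aggregate meta-learner weight",
                    xlab = "model family", ...)
  invisible(x)
}
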