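# End-to-end orchestration: config validation, the full split -> cohort ->
# indices -> tune -> stack -> evaluate -> explain pipeline, and report
# artifacts written to a run directory.

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full run. Defaults mirror
#' the modeling recipe: 80/20 split, 10-fold x 3-repeat CV, 0.99 PCA variance
#' target, smoothing off, top-20 candidates per family, meta penalty 1e-6.
#' Either `input_csv` or a `simulate` block must be provided.
#'
#' @param input_csv Optional path to a wide-format spectra CSV.
#' @param simulate Optional [synth_config()] used when no CSV is given.
#' @param split List `frac`, `seed`.
#' @param prep List `sg_window`, `variance_target`, `pca_refit`.
#' @param families Base-learner families to tune.
#' @param budgets Configurations per family.
#' @param cv List `folds`, `repeats`, `seed`.
#' @param stack List `top_m`, `lambda`.
#' @param explain List `band_nm`, `repeats`, `seed`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL, simulate = NULL,
                            split = list(frac = 0.8, seed = 2025),
                            prep = list(sg_window = 0, variance_target = 0.99,
                                        pca_refit = "fold"),
                            families = c("plsr", "pcr", "enet", "gpr", "rf", "xgb"),
                            budgets = c(pcr = 20, plsr = 20, enet = 30,
                                        gpr = 20, rf = 60, xgb = 60),
                            cv = list(folds = 10, repeats = 3, seed = 1),
                            stack = list(top_m = 20, lambda = 1e-6),
                            explain = list(band_nm = 10, repeats = 10, seed = 3)) {
  if (is.null(input_csv) && is.null(simulate)) {
    stopf("config needs `input_csv` or a `simulate` block")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "synth_config"))
  if (split$frac <= 0 || split$frac >= 1) stopf("split$frac must be in (0, 1)")
  cv_obj <- cv_spec(cv$folds, cv$repeats, cv$seed)   # validates folds/repeats
  prep_obj <- prep_opts(prep$sg_window, prep$variance_target,
                        prep$pca_refit %||% "fold")
  if (stack$top_m < 1) stopf("stack$top_m must be >= 1")
  if (stack$lambda < 0) stopf("stack$lambda must be >= 0")
  structure(list(input_csv = input_csv, simulate = simulate, split = split,
                 prep = prep_obj, families = families, budgets = budgets,
                 cv = cv_obj, stack = stack, explain = explain),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipeline_config()]; the `simulate`
#' block mirrors [synth_config()], with the sample count spelled
#' `n_samples` (YAML 1.1 reads a bare `n` key as a boolean).
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sb <- y$simulate
    names(sb)[names(sb) == "n_samples"] <- "n"
    sim <- do.call(synth_config, sb)
  }
  args <- y[setdiff(names(y), "simulate")]
  if (!is.null(args$budgets)) args$budgets <- unlist(args$budgets)
  if (!is.null(args$families)) args$families <- as.character(unlist(args$families))
  do.call(pipeline_config, c(args, list(simulate = sim)))
}

#' Run the full dry matter estimation pipeline
#'
#' Executes split -> cohort comparability -> index baselines -> base-learner
#' tuning -> single-model benchmark -> stacking -> test evaluation -> band
#' importance -> residual diagnostics, writing all report artifacts to
#' `out_dir`: `train.csv`/`test.csv`, `cohort.csv`, `index_benchmark.csv`,
#' `enet_indices.csv`, `single_models.csv`, `stack_weights.csv`,
#' `importance.csv`, `residuals.csv`, `metrics.json` and `log.txt`. Runs are
#' idempotent: identical config (and seeds) reproduce identical metrics.
#'
#' @param config A [pipeline_config()] or a YAML path.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted `dm_stack` and all computed
#'   tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  say("stage: data")
  ds <- if (!is.null(config$input_csv)) read_spectra_csv(config$input_csv)
        else generate_dataset(config$simulate)$dataset
  art <- screen_artifacts(ds)
  if (length(flagged_ids(art))) {
    say("artifact screen: removing %d flagged sample(s)", length(flagged_ids(art)))
    ds <- ds[setdiff(ds$ids, flagged_ids(art))]
  }

  say("stage: split (frac %.2f, seed %s)", config$split$frac, config$split$seed)
  sp <- split_dataset(ds, config$split$frac, config$split$seed)
  write_spectra_csv(sp$train, file.path(out_dir, "train.csv"))
  write_spectra_csv(sp$test, file.path(out_dir, "test.csv"))

  say("stage: cohort comparability")
  coh <- cohort_stats(sp$train$dm, sp$test$dm)
  utils::write.csv(cbind(subset = rownames(coh$descriptives), coh$descriptives),
                   file.path(out_dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(coh$tests)) {
    utils::write.csv(coh$tests, file.path(out_dir, "cohort_tests.csv"),
                     row.names = FALSE)
  }

  say("stage: spectral index baselines")
  bench <- index_benchmark(sp$train, sp$test)
  utils::write.csv(bench, file.path(out_dir, "index_benchmark.csv"), row.names = FALSE)
  enet <- enet_on_indices(sp$train, sp$test, seed = config$cv$seed)
  utils::write.csv(data.frame(index = names(enet$coefficients),
                              coefficient = unname(enet$coefficients)),
                   file.path(out_dir, "enet_indices.csv"), row.names = FALSE)

  say("stage: tuning %s", paste(config$families, collapse = ", "))
  tuning <- tune_learners(sp$train, config$families, config$budgets,
                          config$cv, config$prep)

  say("stage: single-model benchmark")
  singles <- single_model_benchmark(tuning, sp$train, sp$test)
  utils::write.csv(singles, file.path(out_dir, "single_models.csv"), row.names = FALSE)

  say("stage: stacking (top_m %d, lambda %g)",
      config$stack$top_m, config$stack$lambda)
  stack <- dm_stack(sp$train, tuning = tuning,
                    top_m = config$stack$top_m, lambda = config$stack$lambda)
  wr <- report_weights(stack)
  utils::write.csv(wr, file.path(out_dir, "stack_weights.csv"), row.names = FALSE)
  p_te <- predict(stack, sp$test)
  stack_rmse <- rmse(sp$test$dm, p_te)
  stack_r2 <- rsq(sp$test$dm, p_te)
  say("stack test RMSE %.3f%%, R2 %.3f", stack_rmse, stack_r2)

  say("stage: band importance")
  imp <- band_permutation_importance(stack, sp$test,
                                     band_nm = config$explain$band_nm,
                                     repeats = config$explain$repeats,
                                     seed = config$explain$seed)
  utils::write.csv(as.data.frame(imp), file.path(out_dir, "importance.csv"),
                   row.names = FALSE)

  say("stage: residual diagnostics")
  res <- residual_diagnostics(stack, sp$test)
  utils::write.csv(data.frame(predicted = res$predicted,
                              residual = res$residuals),
                   file.path(out_dir, "residuals.csv"), row.names = FALSE)

  metrics <- list(
    n_train = n_samples(sp$train), n_test = n_samples(sp$test),
    stack = list(test_rmse = stack_rmse, test_r2 = stack_r2,
                 train_rmse = stack$train_rmse, train_r2 = stack$train_r2,
                 n_members = length(stack$members),
                 intercept = stack$intercept,
                 weight_sum = sum(stack$weights)),
    best_single = as.list(singles[1, c("family", "test_rmse", "test_r2")]),
    enet_indices = list(test_rmse = enet$rmse, test_r2 = enet$r2,
                        n_retained = length(enet$retained)),
    best_index = as.list(bench[1, ]),
    importance_peak_nm = imp$center[which.max(imp$delta_rmse_mean)],
    seeds = list(split = config$split$seed, cv = config$cv$seed,
                 explain = config$explain$seed)
  )
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, logf)
  invisible(list(stack = stack, singles = singles, index_benchmark = bench,
                 enet = enet, cohort = coh, importance = imp, residuals = res,
                 metrics = metrics, train = sp$train, test = sp$test))
}
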