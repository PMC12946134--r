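# End-to-end orchestration: preparation -> each feature-selection
# configuration -> each classifier -> evaluation, plus the batch
# prediction / data-append behaviors of the deployed risk tool.

#' Benchmark configuration
#'
#' @param methods named list of selection configurations. Each entry is a
#'   list with a `method` field (`"filter"`, `"adtree"`, `"cvfe"`,
#'   `"hfe"`, or `"none"` for the full feature set) plus that method's
#'   parameters (filter: `r_threshold`, `alpha`; adtree: `B`; cvfe: `c`,
#'   `e`, `p`, `grid`; hfe: `b`, `beta`). The entry's name labels the
#'   configuration in the comparison table.
#' @param models classifiers to benchmark, subset of `c("rf","svm","xgb")`.
#' @param grids classifier grids, see [default_grids()].
#' @param test_frac stratified test fraction.
#' @param seed master seed for undersampling, splitting, selection and
#'   training.
#' @param nfold CV folds for classifier grid search.
#' @param shap_samples number of test rows explained for the best model
#'   (0 disables the explanation stage).
#' @param shap_background background rows drawn from the training set.
#' @param outdir optional output directory for artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(methods = list(
                         filter = list(method = "filter"),
                         adtree = list(method = "adtree", B = 50),
                         cvfe = list(method = "cvfe", c = 2, e = 5, p = 0.6),
                         hfe_b5_beta50 = list(method = "hfe", b = 5, beta = 50)),
                       models = c("rf", "svm", "xgb"),
                       grids = default_grids(), test_frac = 0.20, seed = 1L,
                       nfold = 10L, shap_samples = 20L, shap_background = 50L,
                       outdir = NULL) {
  if (length(methods) < 1 || length(models) < 1)
    stopf("at least one selection method and one model must be enabled")
  structure(list(methods = methods, models = models, grids = grids,
                 test_frac = test_frac, seed = as.integer(seed),
                 nfold = as.integer(nfold),
                 shap_samples = as.integer(shap_samples),
                 shap_background = as.integer(shap_background),
                 outdir = outdir),
            class = "run_config")
}

run_selection <- function(entry, train_tbl, seed, nfold) {
  m <- entry$method %||% stopf("selection entry lacks a 'method' field")
  switch(m,
    none = selection_result("none", list(), names(train_tbl$data)),
    filter = filter_select(train_tbl,
                           r_threshold = entry$r_threshold %||% 0.90,
                           alpha = entry$alpha %||% 0.001),
    adtree = features_used(adtree(train_tbl, B = entry$B %||% 50,
                                  epsilon = entry$epsilon)),
    cvfe = cvfe_select(train_tbl, config = cvfe_config(
      c = entry$c %||% 2, e = entry$e %||% 5, p = entry$p %||% 0.6,
      seed = seed, grid = entry$grid %||% cvfe_config()$grid,
      nfold = entry$nfold %||% nfold)),
    hfe = hfe_select(train_tbl, b = entry$b %||% 5, beta = entry$beta %||% 50,
                     scheme = entry$scheme %||% "frequency"),
    stopf("unknown selection method '%s'", m))
}

method_config_string <- function(entry) {
  pars <- entry[setdiff(names(entry), c("method", "grid"))]
  if (!length(pars)) return("-")
  paste(names(pars), unlist(lapply(pars, format)), sep = "=", collapse = ", ")
}

#' Run the full selection-by-classifier benchmark
#'
#' Prepares the cohort (missingness filter, complete cases, undersampling,
#' stratified split), runs every configured feature-selection method on
#' the training subset, trains every classifier on each selected feature
#' set, evaluates on the held-out test subset, and explains the best
#' model (highest test accuracy, AUC tie-break) with Shapley
#' attributions. Fully seeded: identical `(cohort, config)` reproduce
#' every output.
#'
#' @param cohort a [cohort_table()].
#' @param config a [run_config()].
#' @return a `benchmark_result`: `comparison` (one row per configuration
#'   x model with the six metrics and CI), `selections` (named list of
#'   [selection_result()]), `best` (row index into `comparison`),
#'   `bundle` (a `model_bundle` for the best model), `shap`
#'   (attribution summary or NULL), `prep_log`.
#' @export
run_benchmark <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "run_config"))
  prep <- prepare_cohort(cohort, test_frac = config$test_frac,
                         seed = config$seed)
  train_tbl <- cohort_rows(prep$table, prep$split$train)
  test_tbl <- cohort_rows(prep$table, prep$split$test)

  rows <- list(); selections <- list(); fitted <- list()
  for (label in names(config$methods)) {
    sel <- run_selection(config$methods[[label]], train_tbl, config$seed,
                         config$nfold)
    selections[[label]] <- sel
    if (!length(sel$selected)) {
      warning(sprintf("selection '%s' retained no features; skipped", label))
      next
    }
    tr <- cohort_features(train_tbl, sel$selected)
    te <- cohort_features(test_tbl, sel$selected)
    tm <- train_models(tr, models = config$models, grids = config$grids,
                       seed = config$seed, nfold = config$nfold)
    for (algo in names(tm$fits)) {
      rep <- evaluate(tm$fits[[algo]]$model, te)
      key <- paste(label, algo, sep = "/")
      fitted[[key]] <- tm$fits[[algo]]$model
      rows[[key]] <- data.frame(
        method = config$methods[[label]]$method, configuration = label,
        config_params = method_config_string(config$methods[[label]]),
        n_features = length(sel$selected), model = algo,
        accuracy = rep$accuracy, ci_lower = rep$ci95[["lower"]],
        ci_upper = rep$ci95[["upper"]], precision = rep$precision,
        recall = rep$recall, f1 = rep$f1, auc = rep$auc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stopf("benchmark produced no results")
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  best <- order(-comparison$accuracy, -comparison$auc)[1]
  best_label <- comparison$configuration[best]
  best_model <- fitted[[paste(best_label, comparison$model[best], sep = "/")]]
  sel_feats <- selections[[best_label]]$selected

  bundle <- new_bundle(best_model, comparison$model[best], sel_feats,
                       cohort_features(train_tbl, sel_feats), config)

  shap <- NULL
  if (config$shap_samples > 0) {
    set.seed(derive_seed(config$seed, "shap_rows"))
    bg_df <- train_tbl$data[sample(nrow(train_tbl$data),
                                   min(config$shap_background,
                                       nrow(train_tbl$data))),
                            sel_feats, drop = FALSE]
    ex_df <- test_tbl$data[sample(nrow(test_tbl$data),
                                  min(config$shap_samples,
                                      nrow(test_tbl$data))),
                           sel_feats, drop = FALSE]
    attr_m <- shap_explain(best_model, bg_df, ex_df, seed = config$seed)
    shap <- list(attribution = attr_m,
                 summary = attribution_summary(attr_m, ex_df,
                                               train_tbl$kinds[sel_feats]))
  }

  res <- structure(list(comparison = comparison, selections = selections,
                        best = best, bundle = bundle, shap = shap,
                        prep_log = prep$log, seed = config$seed),
                   class = "benchmark_result")
  if (!is.null(config$outdir)) write_benchmark_artifacts(res, config$outdir)
  res
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result:\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  b <- x$comparison[x$best, ]
  cat(sprintf("best: %s + %s (accuracy %.4f, AUC %.4f)\n",
              b$configuration, b$model, b$accuracy, b$auc))
  invisible(x)
}

write_benchmark_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  num <- c("accuracy", "ci_lower", "ci_upper", "precision", "recall", "f1", "auc")
  cmp <- res$comparison
  cmp[num] <- lapply(cmp[num], function(v) sprintf("%.4f", v))
  utils::write.csv(cmp, file.path(outdir, "comparison.csv"), row.names = FALSE)
  for (label in names(res$selections))
    writeLines(res$selections[[label]]$selected,
               file.path(outdir, sprintf("features_%s.txt", label)))
  save_bundle(res$bundle, file.path(outdir, "best_model_bundle.rds"))
  if (!is.null(res$shap)) {
    utils::write.csv(res$shap$summary$ranking,
                     file.path(outdir, "shap_ranking.csv"), row.names = FALSE)
    grDevices::png(file.path(outdir, "shap_bar.png"), width = 800, height = 600)
    plot(res$shap$summary)
    grDevices::dev.off()
  }
  invisible(outdir)
}

# model bundle --------------------------------------------------------------

new_bundle <- function(model, model_id, features, train_tbl, config) {
  structure(list(model = model, model_id = model_id, features = features,
                 kinds = train_tbl$kinds, levels = lapply(train_tbl$data,
                   function(c) if (is.factor(c)) levels(c) else NULL),
                 train_data = train_tbl$data, train_y = train_tbl$outcome,
                 outcome_name = train_tbl$outcome_name,
                 grids = config$grids, nfold = config$nfold,
                 seed = config$seed, threshold = 0.5,
                 log = sprintf("trained %s on %d rows x %d features (seed %d)",
                               model_id, nrow(train_tbl$data),
                               length(features), config$seed)),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle: %s on %d features, %d training rows\n",
              x$model_id, length(x$features), nrow(x$train_data)))
  cat("log:\n"); cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Save / load a model bundle
#' @param bundle a `model_bundle`.
#' @param path RDS path.
#' @return `path` / the loaded bundle.
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) readRDS(path)

# batch prediction ----------------------------------------------------------

#' Batch prediction with probabilities and per-row attributions
#'
#' Validates the input against the bundle's feature schema, predicts the
#' risk probability and class for every valid row, and (optionally)
#' attaches the top contributing features per row from a Shapley
#' explanation against the bundle's training data.
#'
#' @param bundle a `model_bundle`.
#' @param input CSV path or data.frame of new rows.
#' @param shap if `TRUE`, compute per-row attributions and report the
#'   `top_k` strongest signed contributors.
#' @param top_k contributors to list per row.
#' @param out optional output CSV path.
#' @return a data.frame (class `prediction_records`): `row_id`,
#'   `probability`, `class`, and `top_features` when `shap = TRUE`.
#'   Rows with invalid values are reported in `attr(, "row_errors")` and
#'   excluded from prediction.
#' @export
predict_batch <- function(bundle, input, shap = FALSE, top_k = 3L, out = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  df <- if (is.character(input))
    utils::read.csv(input, stringsAsFactors = FALSE, na.strings = "")
  else as.data.frame(input)
  missing <- setdiff(bundle$features, names(df))
  if (length(missing))
    stopf("input is missing required column(s): %s",
          paste(missing, collapse = ", "))
  df <- df[, bundle$features, drop = FALSE]
  errors <- list()
  for (nm in bundle$features) {
    if (bundle$kinds[[nm]] == "continuous") {
      v <- suppressWarnings(as.numeric(df[[nm]]))
      bad <- which(is.na(v) & !is.na(df[[nm]]))
      for (r in bad)
        errors[[length(errors) + 1]] <- data.frame(
          row = r, column = nm,
          problem = sprintf("non-numeric value '%s'", df[[nm]][r]))
      df[[nm]] <- v
    } else {
      lv <- bundle$levels[[nm]]
      df[[nm]] <- factor(as.character(df[[nm]]), levels = lv)
    }
    bad_na <- which(is.na(df[[nm]]))
    for (r in bad_na)
      if (!any(vapply(errors, function(e) e$row == r && e$column == nm,
                      logical(1))))
        errors[[length(errors) + 1]] <- data.frame(
          row = r, column = nm, problem = "missing or out-of-schema value")
  }
  row_errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(0), column = character(0), problem = character(0))
  valid <- setdiff(seq_len(nrow(df)), unique(row_errors$row))
  recs <- data.frame(row_id = valid,
                     probability = numeric(length(valid)),
                     class = integer(length(valid)))
  if (length(valid)) {
    p <- predict_prob(bundle$model, df[valid, , drop = FALSE])
    recs$probability <- p
    recs$class <- as.integer(p >= bundle$threshold)
    if (shap) {
      set.seed(derive_seed(bundle$seed, "batch_shap"))
      bg <- bundle$train_data[sample(nrow(bundle$train_data),
                                     min(25, nrow(bundle$train_data))),
                              bundle$features, drop = FALSE]
      at <- shap_explain(bundle$model, bg, df[valid, , drop = FALSE],
                         seed = bundle$seed)
      recs$top_features <- apply(at$phi, 1, function(row) {
        o <- order(-abs(row))[seq_len(min(top_k, length(row)))]
        paste(sprintf("%s=%+.3f", names(row)[o], row[o]), collapse = "; ")
      })
    }
  }
  attr(recs, "row_errors") <- row_errors
  class(recs) <- c("prediction_records", class(recs))
  if (!is.null(out)) utils::write.csv(recs, out, row.names = FALSE)
  recs
}

# data append ---------------------------------------------------------------

#' Append training data and refit
#'
#' Validates new rows against the bundle's schema (feature names, kinds
#' and categorical levels plus the outcome column), appends them to the
#' bundle's training store, refits the model with the stored
#' hyperparameter search space and seed, and records the event in the
#' provenance log. Appending zero rows leaves the model untouched.
#'
#' @param bundle a `model_bundle`.
#' @param new_rows CSV path or data.frame with the bundle's feature
#'   columns plus the outcome column.
#' @return the refreshed `model_bundle`.
#' @export
append_training_data <- function(bundle, new_rows) {
  stopifnot(inherits(bundle, "model_bundle"))
  df <- if (is.character(new_rows))
    utils::read.csv(new_rows, stringsAsFactors = FALSE, na.strings = "")
  else as.data.frame(new_rows)
  need <- c(bundle$features, bundle$outcome_name)
  diff_missing <- setdiff(need, names(df))
  diff_extra <- setdiff(names(df), need)
  if (length(diff_missing) || length(diff_extra))
    stopf("schema mismatch; missing: [%s]; unexpected: [%s]",
          paste(diff_missing, collapse = ", "),
          paste(diff_extra, collapse = ", "))
  if (nrow(df) == 0) {
    bundle$log <- c(bundle$log, "append 0 rows; model unchanged")
    return(bundle)
  }
  y_new <- as.integer(df[[bundle$outcome_name]])
  if (!all(y_new %in% c(0L, 1L))) stopf("schema mismatch; outcome must be 0/1")
  df <- df[, bundle$features, drop = FALSE]
  for (nm in bundle$features) {
    if (bundle$kinds[[nm]] == "continuous") {
      v <- suppressWarnings(as.numeric(df[[nm]]))
      if (anyNA(v)) stopf("schema mismatch; non-numeric values in '%s'", nm)
      df[[nm]] <- v
    } else {
      lv <- bundle$levels[[nm]]
      bad <- setdiff(unique(as.character(df[[nm]])), lv)
      if (length(bad))
        stopf("schema mismatch; unknown level(s) in '%s': %s", nm,
              paste(bad, collapse = ", "))
      df[[nm]] <- factor(as.character(df[[nm]]), levels = lv)
    }
  }
  bundle$train_data <- rbind(bundle$train_data, df)
  bundle$train_y <- c(bundle$train_y, y_new)
  tm <- train_models(bundle$train_data, bundle$train_y,
                     models = bundle$model_id,
                     grids = bundle$grids, seed = bundle$seed,
                     nfold = bundle$nfold)
  bundle$model <- tm$fits[[bundle$model_id]]$model
  bundle$log <- c(bundle$log,
                  sprintf("append %d rows (total %d); refit %s with seed %d",
                          nrow(df), nrow(bundle$train_data), bundle$model_id,
                          bundle$seed))
  bundle
}
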