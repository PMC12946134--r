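# Classifier training with small grid search by stratified k-fold CV.
# Three algorithms: random forest, RBF-kernel SVM with probability
# calibration, and gradient boosting. Grids are deliberately small and
# replaceable.

#' Default hyperparameter grids
#' @return named list of per-algorithm grids.
#' @export
default_grids <- function() {
  list(
    rf = list(ntree = c(200, 500), nodesize = c(1, 5)),
    svm = list(cost = c(0.1, 1, 10), gamma = c(NA, 0.01)),  # NA = 1/p default
    xgb = list(max_depth = c(3, 5), eta = c(0.1, 0.3), nrounds = c(50, 100))
  )
}

fit_one <- function(algo, xm, y, pars, seed) {
  set.seed(seed)
  if (algo == "rf") {
    m <- randomForest::randomForest(xm, factor(y, levels = c(0, 1)),
                                    ntree = pars$ntree, nodesize = pars$nodesize)
  } else if (algo == "svm") {
    gamma <- if (is.na(pars$gamma)) 1 / ncol(xm) else pars$gamma
    m <- e1071::svm(xm, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = pars$cost, gamma = gamma, probability = TRUE)
  } else if (algo == "xgb") {
    m <- fit_xgb(xm, y, pars$max_depth, pars$eta, pars$nrounds, seed)
  } else stopf("unknown algorithm '%s'", algo)
  attr(m, "model_id") <- algo
  attr(m, "feature_names") <- colnames(xm)
  m
}

#' Class-1 probability predictions
#'
#' Dispatches over the three supported model types (and [adtree()], whose
#' margin is mapped through the logistic function).
#'
#' @param model fitted model.
#' @param newdata data.frame or numeric matrix of features.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, newdata) {
  df <- if (inherits(newdata, "cohort_table")) newdata$data else newdata
  feats <- attr(model, "feature_names")
  if (inherits(model, "adtree"))
    return(stats::plogis(2 * predict(model, df)))
  xm <- if (is.matrix(df)) df else as_numeric_matrix(as.data.frame(df))
  if (!is.null(feats)) {
    missing <- setdiff(feats, colnames(xm))
    if (length(missing)) stopf("missing required column(s): %s",
                               paste(missing, collapse = ", "))
    xm <- xm[, feats, drop = FALSE]
  }
  if (inherits(model, "randomForest")) {
    unname(predict(model, xm, type = "prob")[, "1"])
  } else if (inherits(model, "svm")) {
    pr <- attr(predict(model, xm, probability = TRUE), "probabilities")
    unname(pr[, "1"])
  } else if (inherits(model, c("xgb.Booster"))) {
    predict(model, xgboost::xgb.DMatrix(xm, nthread = 1))
  } else {
    p <- predict(model, xm)
    as.numeric(p)
  }
}

#' Train tuned classifiers
#'
#' For each requested algorithm, searches its grid by stratified
#' `nfold`-fold cross-validated accuracy (single-combination grids skip
#' the search) and refits the best combination on the full training set.
#'
#' @param train a [cohort_table()] or data.frame of training features.
#' @param labels training labels (ignored for a `cohort_table`).
#' @param models algorithms to fit, subset of `c("rf", "svm", "xgb")`.
#' @param grids per-algorithm grids, as [default_grids()].
#' @param seed integer seed.
#' @param nfold CV folds for the grid search (reduced with a warning if a
#'   class is smaller).
#' @return a `trained_models` list: one element per algorithm with
#'   `model`, `params`, `cv_accuracy`; plus `features` and `seed`.
#' @export
train_models <- function(train, labels = NULL, models = c("rf", "svm", "xgb"),
                         grids = default_grids(), seed = 1L, nfold = 10L) {
  if (inherits(train, "cohort_table")) {
    labels <- train$outcome; df <- train$data
  } else {
    df <- as.data.frame(train)
    if (is.null(labels)) stopf("labels are required")
  }
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stopf("both classes must be present in training data")
  xm <- as_numeric_matrix(df)
  kmax <- min(sum(y == 1), sum(y == 0))
  if (kmax < nfold) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    nfold, kmax))
    nfold <- max(2L, kmax)
  }
  out <- list()
  for (algo in models) {
    grid <- grids[[algo]]
    rows <- do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE,
                                              stringsAsFactors = FALSE)))
    cvacc <- NA_real_
    if (nrow(rows) > 1) {
      fold <- make_folds(y, nfold, derive_seed(seed, paste0(algo, "_folds")))
      acc <- numeric(nrow(rows))
      for (g in seq_len(nrow(rows))) {
        correct <- 0L
        for (k in seq_len(nfold)) {
          tr <- fold != k
          m <- fit_one(algo, xm[tr, , drop = FALSE], y[tr],
                       as.list(rows[g, , drop = FALSE]),
                       derive_seed(seed, paste0(algo, g, "f", k)))
          p <- predict_prob(m, xm[!tr, , drop = FALSE])
          correct <- correct + sum((p >= 0.5) == (y[!tr] == 1))
        }
        acc[g] <- correct / length(y)
      }
      best <- which.max(acc)
      cvacc <- acc[best]
      rows <- rows[best, , drop = FALSE]
    }
    pars <- as.list(rows[1, , drop = FALSE])
    out[[algo]] <- list(model = fit_one(algo, xm, y, pars,
                                        derive_seed(seed, paste0(algo, "_final"))),
                        params = pars, cv_accuracy = cvacc)
  }
  structure(list(fits = out, features = colnames(xm), seed = as.integer(seed)),
            class = "trained_models")
}

#' @export
print.trained_models <- function(x, ...) {
  cat(sprintf("trained_models: %s on %d features\n",
              paste(names(x$fits), collapse = ", "), length(x$features)))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %s: %s (CV acc %s)\n", nm,
                paste(names(f$params), unlist(lapply(f$params, format)),
                      sep = "=", collapse = ", "),
                if (is.na(f$cv_accuracy)) "not searched"
                else sprintf("%.4f", f$cv_accuracy)))
  }
  invisible(x)
}
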