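# Cross-validated feature evaluation: repeated stratified partition into c
# subsets, per-subset gradient-boosting importance selection, intersection
# within a repetition, consensus threshold p across the e repetitions.

#' CVFE configuration
#'
#' @param c number of subsets per repetition (each subset gets its own
#'   gradient-boosting fit).
#' @param e number of repetitions.
#' @param p consensus fraction in `[0, 1]`: a feature is kept when it
#'   appears in at least `ceiling(p * e)` of the `e` intersected sets.
#' @param seed integer seed.
#' @param grid named list of hyperparameter vectors for the per-subset
#'   gradient-boosting fits (`max_depth`, `eta`, `nrounds`); all
#'   combinations are searched by stratified cross-validation when more
#'   than one combination is supplied.
#' @param nfold folds for the internal grid search.
#' @return a `cvfe_config` object.
#' @export
cvfe_config <- function(c = 2L, e = 5L, p = 0.6, seed = 1L,
                        grid = list(max_depth = c(3, 5), eta = c(0.1, 0.3),
                                    nrounds = c(50, 100)),
                        nfold = 10L) {
  if (c < 1 || e < 1) stopf("c and e must be >= 1")
  if (p < 0 || p > 1) stopf("p must be in [0, 1]")
  structure(list(c = as.integer(c), e = as.integer(e), p = p,
                 seed = as.integer(seed), grid = grid,
                 nfold = as.integer(nfold)),
            class = "cvfe_config")
}

xgb_grid_rows <- function(grid) {
  do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE)))
}

fit_xgb <- function(xm, y, max_depth, eta, nrounds, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(xm, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Per-subset influential features
#'
#' Fits a gradient-boosted tree classifier on one data subset (grid search
#' by stratified `nfold`-fold CV accuracy when the grid has more than one
#' combination) and returns the features with strictly positive gain
#' importance.
#'
#' @param x data.frame or numeric matrix of features.
#' @param y binary labels (0/1).
#' @param grid hyperparameter grid as in [cvfe_config()].
#' @param seed integer seed.
#' @param nfold folds for the grid search; reduced with a warning when a
#'   class has fewer rows than folds.
#' @return character vector of feature names with positive importance.
#' @export
per_subset_importance <- function(x, y, grid = cvfe_config()$grid, seed = 1L,
                                  nfold = 10L) {
  xm <- if (is.matrix(x)) x else as_numeric_matrix(as.data.frame(x))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("both classes must be present in the subset")
  rows <- xgb_grid_rows(grid)
  choice <- rows[1, , drop = FALSE]
  if (nrow(rows) > 1) {
    kmax <- min(sum(y == 1), sum(y == 0))
    if (kmax < nfold) {
      warning(sprintf("reducing folds from %d to %d (smallest class size)",
                      nfold, kmax))
      nfold <- max(2L, kmax)
    }
    fold <- make_folds(y, nfold, derive_seed(seed, "cvfe_folds"))
    acc <- numeric(nrow(rows))
    for (g in seq_len(nrow(rows))) {
      correct <- 0L
      for (k in seq_len(nfold)) {
        tr <- fold != k
        bst <- fit_xgb(xm[tr, , drop = FALSE], y[tr], rows$max_depth[g],
                       rows$eta[g], rows$nrounds[g],
                       derive_seed(seed, paste0("g", g, "f", k)))
        p <- predict(bst, xgboost::xgb.DMatrix(xm[!tr, , drop = FALSE],
                                               nthread = 1))
        correct <- correct + sum((p >= 0.5) == (y[!tr] == 1))
      }
      acc[g] <- correct / length(y)
    }
    choice <- rows[which.max(acc), , drop = FALSE]
  }
  bst <- fit_xgb(xm, y, choice$max_depth, choice$eta, choice$nrounds,
                 derive_seed(seed, "final"))
  imp <- xgboost::xgb.importance(model = bst)
  feats <- imp$Feature[imp$Gain > 0]
  colnames(xm)[colnames(xm) %in% feats]
}

#' Cross-validated consensus feature selection
#'
#' For each of `e` repetitions the rows are randomly partitioned into `c`
#' class-stratified subsets; each subset contributes the positive-gain
#' feature set of a tuned gradient-boosting fit, and the repetition keeps
#' the intersection of its `c` sets. The final selection contains the
#' features present in at least `ceiling(p * e)` of the `e` intersected
#' sets.
#'
#' @param table a [cohort_table()], or data.frame of features.
#' @param y labels (ignored for a `cohort_table`).
#' @param config a [cvfe_config()].
#' @return a [selection_result()]; `$membership` on the result holds the
#'   feature-by-repetition membership matrix.
#' @export
cvfe_select <- function(table, y = NULL, config = cvfe_config()) {
  if (inherits(table, "cohort_table")) {
    df <- table$data; y <- table$outcome
  } else {
    df <- as.data.frame(table)
    if (is.null(y)) stopf("y is required when table is not a cohort_table")
  }
  y <- as.integer(y)
  if (config$c > min(sum(y == 1), sum(y == 0)))
    stopf("c (%d) exceeds the smaller class size", config$c)
  xm <- as_numeric_matrix(df)
  membership <- matrix(FALSE, ncol(df), config$e,
                       dimnames = list(names(df), NULL))
  for (rep_i in seq_len(config$e)) {
    set.seed(derive_seed(config$seed, paste0("cvfe_rep", rep_i)))
    assign <- integer(length(y))
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(config$c), length(idx))
    }
    sets <- vector("list", config$c)
    for (s in seq_len(config$c)) {
      rows <- assign == s
      sets[[s]] <- per_subset_importance(
        xm[rows, , drop = FALSE], y[rows], grid = config$grid,
        seed = derive_seed(config$seed, paste0("rep", rep_i, "sub", s)),
        nfold = config$nfold)
    }
    membership[Reduce(intersect, sets), rep_i] <- TRUE
  }
  need <- ceiling(config$p * config$e)
  selected <- rownames(membership)[rowSums(membership) >= need]
  res <- selection_result("cvfe",
                          list(c = config$c, e = config$e, p = config$p),
                          selected,
                          scores = rowSums(membership) / config$e)
  res$membership <- membership
  res
}

#' Write the CVFE membership audit CSV
#' @param result result of [cvfe_select()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cvfe_audit <- function(result, path) {
  m <- result$membership
  df <- data.frame(feature = rownames(m), m + 0,
                   selected = rownames(m) %in% result$selected)
  names(df)[2:(ncol(m) + 1)] <- paste0("rep", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
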