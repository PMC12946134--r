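# Hypergraph-based feature evaluation. Samples are vertices; every
# observed (feature, discretized value) is a hyperedge over the samples
# sharing that value; the class labels partition the vertex set. Each
# hyperedge is weighted by its stationary mass under the vertex ->
# incident-hyperedge -> member-vertex random walk and scored by how far
# its within-edge class distribution deviates from the global class
# proportions (zero exactly at proportionality, the cut-conductance
# principle); feature scores aggregate their hyperedge scores.

#' Discretize a feature table
#'
#' Continuous features are cut into at most `b` bins (default
#' equal-frequency quantile cuts; equal-width available); categorical
#' features pass through as level codes. Empty bins (from tied quantiles)
#' are dropped, so codes are consecutive integers starting at 1.
#'
#' @param table a [cohort_table()] or data.frame.
#' @param b bin count for continuous features (the study uses 5 and 10).
#' @param scheme `"frequency"` (equal-frequency) or `"width"` (equal-width).
#' @return a `discretized_table`: list with `codes` (integer data.frame),
#'   `bin_edges` (per continuous feature), `b`, `scheme`, and per-code
#'   `value_labels`.
#' @export
discretize <- function(table, b = 5L, scheme = c("frequency", "width")) {
  scheme <- match.arg(scheme)
  if (b < 2) stopf("b must be >= 2")
  if (inherits(table, "cohort_table")) {
    df <- table$data; kinds <- table$kinds
  } else {
    df <- as.data.frame(table)
    kinds <- vapply(df, function(c) if (is.factor(c) || is.character(c))
      "categorical" else "continuous", character(1))
  }
  codes <- list(); edges <- list(); labels <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (kinds[[nm]] == "categorical") {
      f <- factor(x)
      codes[[nm]] <- as.integer(f)
      labels[[nm]] <- levels(f)
    } else {
      x <- as.numeric(x)
      if (length(unique(stats::na.omit(x))) <= 1) {
        codes[[nm]] <- ifelse(is.na(x), NA_integer_, 1L)
        labels[[nm]] <- "all"
        next
      }
      brk <- if (scheme == "frequency") {
        unique(stats::quantile(x, probs = seq(0, 1, length.out = b + 1),
                               na.rm = TRUE, names = FALSE))
      } else {
        seq(min(x, na.rm = TRUE), max(x, na.rm = TRUE), length.out = b + 1)
      }
      if (length(brk) < 2) brk <- range(x, na.rm = TRUE) + c(-1, 1)
      cutf <- cut(x, breaks = brk, include.lowest = TRUE)
      cutf <- droplevels(cutf)
      codes[[nm]] <- as.integer(cutf)
      labels[[nm]] <- levels(cutf)
      edges[[nm]] <- brk
    }
  }
  structure(list(codes = as.data.frame(codes, optional = TRUE),
                 bin_edges = edges, b = as.integer(b), scheme = scheme,
                 value_labels = labels),
            class = "discretized_table")
}

#' Build the sample/feature-value hypergraph
#'
#' One hyperedge per observed (feature, code): the set of samples sharing
#' that discretized value. With complete data every vertex lies on exactly
#' one hyperedge per feature.
#'
#' @param disc a `discretized_table` from [discretize()].
#' @param labels binary class labels (0/1), one per sample.
#' @return a `hypergraph`: list with `n`, `m`, `edges` (data.frame
#'   `feature`, `value`), `members` (list of vertex index vectors),
#'   `labels`.
#' @export
build_hypergraph <- function(disc, labels) {
  stopifnot(inherits(disc, "discretized_table"))
  codes <- disc$codes
  if (anyNA(codes))
    stopf("hypergraph construction requires complete data (run the complete-case filter first)")
  labels <- as.integer(labels)
  if (length(labels) != nrow(codes)) stopf("labels length mismatch")
  feat <- character(0); val <- integer(0); members <- list()
  for (nm in names(codes)) {
    grp <- split(seq_len(nrow(codes)), codes[[nm]])
    feat <- c(feat, rep(nm, length(grp)))
    val <- c(val, as.integer(names(grp)))
    members <- c(members, unname(grp))
  }
  structure(list(n = nrow(codes), m = ncol(codes),
                 edges = data.frame(feature = feat, value = val,
                                    stringsAsFactors = FALSE),
                 members = members, labels = labels,
                 features = names(codes)),
            class = "hypergraph")
}

#' Stationary hyperedge occupancy of the vertex-edge random walk
#'
#' The walk alternates vertex -> uniformly chosen incident hyperedge ->
#' uniformly chosen member vertex. Its stationary mass on a hyperedge is
#' proportional to the edge's degree (its size), i.e. `|e| / sum(|e'|)`;
#' with complete data this equals `|e| / (N * m)`.
#'
#' @param h a [build_hypergraph()] result.
#' @return numeric vector of occupancies, one per hyperedge, summing to 1.
#' @export
random_walk_occupancy <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  sizes <- lengths(h$members)
  sizes / sum(sizes)
}

#' Hyperedge importance
#'
#' `I(e) = occupancy(e) * D(e)` where `D(e)` is the L1 deviation of the
#' within-edge class distribution from the global class proportions.
#' `I(e)` is zero exactly when the edge's class mixture is proportional
#' to the overall class sizes, and grows with the total-variation
#' deviation at fixed edge size.
#'
#' @param h a [build_hypergraph()] result.
#' @param edge optional edge index; if omitted, all edge importances are
#'   returned.
#' @return numeric importance value(s).
#' @export
edge_importance <- function(h, edge = NULL) {
  stopifnot(inherits(h, "hypergraph"))
  occ <- random_walk_occupancy(h)
  glob <- c(mean(h$labels == 0), mean(h$labels == 1))
  dev <- vapply(h$members, function(v) {
    inside <- c(mean(h$labels[v] == 0), mean(h$labels[v] == 1))
    sum(abs(inside - glob))
  }, numeric(1))
  imp <- occ * dev
  if (is.null(edge)) imp else imp[edge]
}

#' Aggregate hyperedge importances into feature scores
#'
#' @param h a [build_hypergraph()] result.
#' @return an `hfe_scores` object: `edge_table` (feature, value, size,
#'   occupancy, deviation, importance), `feature_score` (named vector in
#'   column order), and `ranking` (feature names by descending score,
#'   ties broken by column order).
#' @export
feature_scores <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  occ <- random_walk_occupancy(h)
  imp <- edge_importance(h)
  et <- cbind(h$edges,
              size = lengths(h$members), occupancy = occ,
              deviation = ifelse(occ > 0, imp / occ, 0), importance = imp)
  fs <- vapply(h$features, function(f) sum(imp[et$feature == f]), numeric(1))
  ranking <- h$features[order(-fs, seq_along(fs))]
  structure(list(edge_table = et, feature_score = fs, ranking = ranking),
            class = "hfe_scores")
}

#' @export
print.hfe_scores <- function(x, ...) {
  cat(sprintf("hfe_scores: %d features, %d hyperedges\n",
              length(x$feature_score), nrow(x$edge_table)))
  print(utils::head(data.frame(feature = x$ranking,
                               score = x$feature_score[x$ranking],
                               row.names = NULL), 10))
  invisible(x)
}

#' Select the top fraction of features by hypergraph score
#'
#' Retains the top `z = round_half_up(beta_percent/100 * m)` features by
#' aggregated importance (for the study's 31 candidates this gives 8, 16
#' and 23 features at beta 25, 50 and 75).
#'
#' @param scores an `hfe_scores` object.
#' @param beta_percent selected percentage in (0, 100].
#' @param m total feature count (defaults to the number scored).
#' @return a [selection_result()].
#' @export
select_top_beta <- function(scores, beta_percent, m = length(scores$feature_score)) {
  stopifnot(inherits(scores, "hfe_scores"))
  if (beta_percent <= 0 || beta_percent > 100)
    stopf("beta_percent must be in (0, 100]")
  z <- round_half_up(beta_percent / 100 * m)
  z <- min(z, length(scores$ranking))
  selection_result("hfe", list(beta = beta_percent, m = m, z = z),
                   scores$ranking[seq_len(z)],
                   scores = scores$feature_score)
}

#' Hypergraph feature evaluation, end to end
#'
#' Discretize, build the hypergraph, score and select.
#'
#' @param table a [cohort_table()] (complete cases) or data.frame.
#' @param y labels (ignored for a `cohort_table`).
#' @param b bin count.
#' @param beta selected percentage.
#' @param scheme binning scheme, see [discretize()].
#' @return a [selection_result()]; the `hfe_scores` object is attached as
#'   `$hfe`.
#' @export
hfe_select <- function(table, y = NULL, b = 5L, beta = 50, scheme = "frequency") {
  if (inherits(table, "cohort_table")) {
    y <- table$outcome
  } else if (is.null(y)) stopf("y is required when table is not a cohort_table")
  disc <- discretize(table, b = b, scheme = scheme)
  h <- build_hypergraph(disc, y)
  sc <- feature_scores(h)
  res <- select_top_beta(sc, beta)
  res$params$b <- b
  res$hfe <- sc
  res
}

#' Write hypergraph scores as CSV
#' @param scores an `hfe_scores` object.
#' @param path output CSV path.
#' @param selected optional character vector flagged as selected.
#' @return `path`, invisibly.
#' @export
write_hfe_scores_csv <- function(scores, path, selected = NULL) {
  rank_of <- stats::setNames(seq_along(scores$ranking), scores$ranking)
  df <- data.frame(feature = names(scores$feature_score),
                   score = unname(scores$feature_score),
                   rank = unname(rank_of[names(scores$feature_score)]),
                   selected = names(scores$feature_score) %in% (selected %||% character(0)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dump hyperedges as an edge-list text file
#'
#' One line per hyperedge: `feature<TAB>value<TAB>space-separated member
#' indices` — handy for cross-checking against independent oracles.
#' @param h a [build_hypergraph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(h, path) {
  lines <- vapply(seq_along(h$members), function(i) {
    sprintf("%s\t%d\t%s", h$edges$feature[i], h$edges$value[i],
            paste(h$members[[i]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
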