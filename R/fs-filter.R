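# Classical two-step redundancy filter: Pearson correlation among
# continuous features, pairwise chi-squared association among categorical
# features. Pairs are scanned in lexicographic order of column indices;
# when a pair is flagged the later column is dropped and pairs involving
# it are skipped.

#' Prune highly correlated continuous features
#'
#' Computes Pearson correlations on pairwise-complete observations among
#' the continuous features and, for every pair with `|r| >=
#' r_threshold`, removes the member that appears later in column order.
#' No surviving pair is correlated at or above the threshold.
#'
#' @param table a [cohort_table()] (or data.frame of numeric columns).
#' @param r_threshold absolute correlation threshold, default 0.90.
#' @return a [selection_result()] over the continuous features.
#' @export
correlation_prune <- function(table, r_threshold = 0.90) {
  df <- if (inherits(table, "cohort_table")) {
    table$data[, table$kinds == "continuous", drop = FALSE]
  } else as.data.frame(table)
  nms <- names(df)
  removed <- character(0)
  audit <- list()
  if (length(nms) >= 2) {
    cm <- suppressWarnings(stats::cor(df, use = "pairwise.complete.obs"))
    for (i in seq_len(length(nms) - 1)) {
      if (nms[i] %in% removed) next
      for (j in seq((i + 1), length(nms))) {
        if (nms[j] %in% removed) next
        r <- cm[i, j]
        if (!is.na(r) && abs(r) >= r_threshold) {
          removed <- c(removed, nms[j])
          audit[[length(audit) + 1]] <- data.frame(
            feature = nms[j], reason = "abs correlation >= threshold",
            partner = nms[i], statistic = r, p_value = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  selection_result("pearson_filter", list(r_threshold = r_threshold),
                   setdiff(nms, removed),
                   audit = if (length(audit)) do.call(rbind, audit) else NULL)
}

#' Prune associated categorical features
#'
#' Pairwise chi-squared tests (no continuity correction) among the
#' categorical features; for every pair with `p <= alpha` the later column
#' is removed.
#'
#' @param table a [cohort_table()] (or data.frame of factor columns).
#' @param alpha association p-value threshold, default 0.001.
#' @return a [selection_result()] over the categorical features.
#' @export
association_prune <- function(table, alpha = 0.001) {
  df <- if (inherits(table, "cohort_table")) {
    table$data[, table$kinds == "categorical", drop = FALSE]
  } else as.data.frame(table)
  nms <- names(df)
  removed <- character(0)
  audit <- list()
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) {
      if (nms[i] %in% removed) next
      for (j in seq((i + 1), length(nms))) {
        if (nms[j] %in% removed) next
        ok <- !is.na(df[[i]]) & !is.na(df[[j]])
        tab <- base::table(droplevels(factor(df[[i]][ok])),
                           droplevels(factor(df[[j]][ok])))
        if (any(dim(tab) < 2)) next
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        if (!is.na(ht$p.value) && ht$p.value <= alpha) {
          removed <- c(removed, nms[j])
          audit[[length(audit) + 1]] <- data.frame(
            feature = nms[j], reason = "chi-squared p <= alpha",
            partner = nms[i], statistic = unname(ht$statistic),
            p_value = ht$p.value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  selection_result("chisq_filter", list(alpha = alpha),
                   setdiff(nms, removed),
                   audit = if (length(audit)) do.call(rbind, audit) else NULL)
}

#' Two-step correlation + association filter
#'
#' [correlation_prune()] on the continuous block followed by
#' [association_prune()] on the categorical block; survivors are returned
#' in original column order with the combined audit trail.
#'
#' @param table a [cohort_table()].
#' @param r_threshold absolute Pearson correlation threshold.
#' @param alpha chi-squared p-value threshold.
#' @return a [selection_result()] over all features.
#' @export
filter_select <- function(table, r_threshold = 0.90, alpha = 0.001) {
  stopifnot(inherits(table, "cohort_table"))
  rc <- correlation_prune(table, r_threshold)
  ra <- association_prune(table, alpha)
  survivors <- union(rc$selected, ra$selected)
  selected <- names(table$data)[names(table$data) %in% survivors]
  selection_result("pearson_chisq_filter",
                   list(r_threshold = r_threshold, alpha = alpha),
                   selected, audit = rbind(rc$audit, ra$audit))
}
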