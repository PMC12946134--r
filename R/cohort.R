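#' Typed cohort table
#'
#' A `cohort_table` holds a participants-by-features table of mixed
#' continuous/categorical clinical variables plus a binary outcome
#' (1 = at risk, 0 = not at risk). Categorical columns are stored as
#' factors with their declared levels; missing entries are `NA`.
#'
#' @param data data.frame of feature columns (continuous numeric or factor).
#' @param outcome integer/numeric vector of 0/1 outcome values, one per row.
#' @param kinds named character vector mapping every feature name to
#'   `"continuous"` or `"categorical"`. If omitted, factors are categorical
#'   and numeric columns continuous.
#' @param outcome_name column name used when the table is written to CSV.
#'
#' @return An object of class `cohort_table` with elements `data`
#'   (features only), `outcome`, `kinds`, `outcome_name`.
#' @export
cohort_table <- function(data, outcome, kinds = NULL, outcome_name = "CVD") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (length(outcome) != nrow(data))
    stopf("outcome length (%d) != row count (%d)", length(outcome), nrow(data))
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L)))
    stopf("outcome must be binary 0/1")
  if (is.null(kinds)) {
    kinds <- vapply(data, function(c) if (is.factor(c) || is.character(c))
      "categorical" else "continuous", character(1))
  }
  kinds <- kinds[names(data)]
  if (anyNA(kinds) || !all(kinds %in% c("continuous", "categorical")))
    stopf("kinds must label every feature as continuous or categorical")
  for (nm in names(data)) {
    if (kinds[[nm]] == "categorical" && !is.factor(data[[nm]]))
      data[[nm]] <- factor(data[[nm]])
    if (kinds[[nm]] == "continuous")
      data[[nm]] <- as.numeric(data[[nm]])
  }
  structure(list(data = data, outcome = outcome, kinds = kinds,
                 outcome_name = outcome_name),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d participants x %d features (%d cases / %d controls)\n",
              nrow(x$data), ncol(x$data), sum(x$outcome == 1), sum(x$outcome == 0)))
  cat(sprintf("  continuous: %d, categorical: %d, missing cells: %d\n",
              sum(x$kinds == "continuous"), sum(x$kinds == "categorical"),
              sum(is.na(x$data))))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

#' Row subset of a cohort table
#' @param table a `cohort_table`.
#' @param idx integer row indices to keep.
#' @return a `cohort_table` with the selected rows.
#' @export
cohort_rows <- function(table, idx) {
  stopifnot(inherits(table, "cohort_table"))
  cohort_table(table$data[idx, , drop = FALSE], table$outcome[idx],
               table$kinds, table$outcome_name)
}

#' Column subset of a cohort table
#' @param table a `cohort_table`.
#' @param features character vector of feature names to keep.
#' @return a `cohort_table` with the selected feature columns.
#' @export
cohort_features <- function(table, features) {
  stopifnot(inherits(table, "cohort_table"))
  missing <- setdiff(features, names(table$data))
  if (length(missing)) stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
  cohort_table(table$data[, features, drop = FALSE], table$outcome,
               table$kinds[features], table$outcome_name)
}

#' Write a cohort table as CSV
#'
#' Header row of NHANES-style feature codes plus the outcome column;
#' missing values are written as empty strings. A `<path>.meta.tsv`
#' sidecar records each feature's kind (and levels), so NHANES-style
#' numerically coded categorical variables keep their type on re-read.
#'
#' @param table a `cohort_table`.
#' @param path output CSV path.
#' @param meta write the type sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path, meta = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  df <- table$data
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  df[[table$outcome_name]] <- table$outcome
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (meta) {
    md <- data.frame(feature = names(table$data),
                     kind = unname(table$kinds),
                     levels = vapply(table$data, function(c)
                       if (is.factor(c)) paste(levels(c), collapse = "|")
                       else "", character(1)))
    utils::write.table(md, paste0(path, ".meta.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path written by [write_cohort_csv()] (or any CSV with the
#'   same layout).
#' @param kinds named character vector of feature kinds; if `NULL` and a
#'   `<path>.meta.tsv` sidecar exists it is used, otherwise numeric columns
#'   are treated as continuous and the rest as categorical.
#' @param levels optional named list of level sets for categorical features.
#' @param outcome_name name of the binary outcome column.
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path, kinds = NULL, levels = NULL,
                            outcome_name = "CVD") {
  meta_path <- paste0(path, ".meta.tsv")
  if (is.null(kinds) && file.exists(meta_path)) {
    md <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    kinds <- stats::setNames(md$kind, md$feature)
    if (is.null(levels))
      levels <- stats::setNames(lapply(md$levels, function(s)
        if (nzchar(s)) strsplit(s, "|", fixed = TRUE)[[1]] else NULL),
        md$feature)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!outcome_name %in% names(df))
    stopf("outcome column '%s' not found in %s", outcome_name, path)
  outcome <- df[[outcome_name]]
  df[[outcome_name]] <- NULL
  if (!is.null(kinds)) {
    for (nm in names(df)) {
      if (identical(kinds[[nm]], "categorical")) {
        lv <- if (!is.null(levels[[nm]])) levels[[nm]] else sort(unique(stats::na.omit(df[[nm]])))
        df[[nm]] <- factor(df[[nm]], levels = lv)
      }
    }
  }
  cohort_table(df, outcome, kinds = kinds, outcome_name = outcome_name)
}

# fraction of missing cells per feature
missing_fraction <- function(table) {
  vapply(table$data, function(c) mean(is.na(c)), numeric(1))
}
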