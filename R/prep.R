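#' Drop features with excessive missingness
#'
#' Removes every feature whose missing-cell fraction *strictly exceeds*
#' `threshold` (a feature missing exactly 30\% of its values is retained
#' under the default). Column order of the survivors is preserved.
#'
#' @param table a [cohort_table()].
#' @param threshold missingness fraction in (0, 1); default 0.30.
#' @return a `cohort_table` without the high-missingness features.
#' @export
drop_high_missingness <- function(table, threshold = 0.30) {
  stopifnot(inherits(table, "cohort_table"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  frac <- missing_fraction(table)
  keep <- names(frac)[frac <= threshold]
  cohort_features(table, keep)
}

#' Keep only complete cases
#'
#' Removes every participant with at least one missing feature value.
#'
#' @param table a [cohort_table()].
#' @return a `cohort_table` with an all-observed feature block.
#' @export
complete_case_filter <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  keep <- which(stats::complete.cases(table$data))
  if (length(keep) == 0) stopf("no complete cases remain")
  cohort_rows(table, keep)
}

#' Randomly undersample the majority class
#'
#' Discards randomly chosen majority-class rows until the classes are
#' exactly balanced at the minority count. Every minority-class row is
#' retained; surviving rows keep their original order.
#'
#' @param table a [cohort_table()] with both outcome classes present.
#' @param seed integer seed for the row draw.
#' @return a balanced `cohort_table`.
#' @export
undersample_majority <- function(table, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  n1 <- sum(table$outcome == 1); n0 <- sum(table$outcome == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  k <- min(n1, n0)
  maj_idx <- which(table$outcome != minority)
  set.seed(derive_seed(seed, "undersample"))
  keep_maj <- sample(maj_idx, k)
  cohort_rows(table, sort(c(which(table$outcome == minority), keep_maj)))
}

#' Stratified train/test split
#'
#' Per-class test counts are `round_half_up(test_frac * class size)`, so a
#' 20\% split of a 335/335 balanced cohort places 67 cases and 67 controls
#' in the test set. Train and test indices are disjoint and exhaustive.
#'
#' @param table a [cohort_table()].
#' @param test_frac test fraction in (0, 1).
#' @param seed integer seed.
#' @return a `split_result`: list with `train`, `test` (integer row index
#'   vectors) and `seed`.
#' @export
stratified_split <- function(table, test_frac = 0.20, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  if (test_frac <= 0 || test_frac >= 1) stopf("test_frac must be in (0, 1)")
  set.seed(derive_seed(seed, "split"))
  test <- integer(0)
  for (cl in c(1L, 0L)) {
    idx <- which(table$outcome == cl)
    k <- round_half_up(test_frac * length(idx))
    k <- max(min(k, length(idx) - 1L), if (length(idx) > 1) 1L else 0L)
    test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  structure(list(train = setdiff(seq_along(table$outcome), test),
                 test = test, seed = as.integer(seed)),
            class = "split_result")
}

#' Descriptive cohort summary
#'
#' Produces the standard baseline-characteristics table: for each
#' categorical feature, level counts and percentages by outcome class with
#' a chi-squared test p-value (no continuity correction by default); for
#' each continuous feature, median (IQR) by class with a Wilcoxon rank-sum
#' p-value (normal approximation with tie correction; exact enumeration
#' when both groups have at most 25 observations and no ties). P-values
#' below 1e-4 are formatted `"<0.0001"`.
#'
#' @param table a [cohort_table()] with both classes present.
#' @param correct logical; continuity-correct 2x2 chi-squared tests.
#' @return data.frame with one row per feature level (categorical) or per
#'   feature (continuous): columns `feature`, `kind`, `level`, `all`,
#'   `cases`, `controls`, `p_value`, `p_formatted`, `test`.
#' @export
descriptive_summary <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  y <- table$outcome
  out <- list()
  for (nm in names(table$data)) {
    x <- table$data[[nm]]
    ok <- !is.na(x)
    if (table$kinds[[nm]] == "categorical") {
      tab <- base::table(x[ok], y[ok])
      p <- tryCatch(
        suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value),
        error = function(e) NA_real_)
      lv <- rownames(tab)
      pct <- function(cnt) sprintf("%d (%.2f)", cnt, 100 * cnt / sum(cnt))
      out[[nm]] <- data.frame(
        feature = nm, kind = "categorical", level = lv,
        all = pct(rowSums(tab)),
        cases = vapply(seq_along(lv), function(i) {
          sprintf("%d (%.2f)", tab[i, "1"], 100 * tab[i, "1"] / sum(tab[, "1"]))
        }, character(1)),
        controls = vapply(seq_along(lv), function(i) {
          sprintf("%d (%.2f)", tab[i, "0"], 100 * tab[i, "0"] / sum(tab[, "0"]))
        }, character(1)),
        p_value = c(p, rep(NA_real_, length(lv) - 1)),
        test = "chi-squared", stringsAsFactors = FALSE)
    } else {
      x1 <- x[ok & y == 1]; x0 <- x[ok & y == 0]
      exact <- length(x1) <= 25 && length(x0) <= 25 &&
        !anyDuplicated(c(x1, x0))
      p <- suppressWarnings(stats::wilcox.test(x1, x0, exact = exact,
                                               correct = FALSE)$p.value)
      miqr <- function(v) sprintf("%.2f (%.2f, %.2f)", stats::median(v),
                                  stats::quantile(v, 0.25), stats::quantile(v, 0.75))
      out[[nm]] <- data.frame(
        feature = nm, kind = "continuous", level = "",
        all = miqr(c(x1, x0)), cases = miqr(x1), controls = miqr(x0),
        p_value = p, test = "wilcoxon", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_formatted <- format_pvalue(res$p_value)
  res
}

#' Full preparation pipeline
#'
#' Missingness filter, complete-case reduction, majority undersampling and
#' stratified split, in that order.
#'
#' @param table a [cohort_table()].
#' @param threshold missingness drop threshold.
#' @param test_frac test fraction.
#' @param seed seed for undersampling and splitting.
#' @return list with `table` (prepared balanced cohort), `split`
#'   (a `split_result`) and per-stage row/feature counts in `log`.
#' @export
prepare_cohort <- function(table, threshold = 0.30, test_frac = 0.20, seed = 1L) {
  t1 <- drop_high_missingness(table, threshold)
  t2 <- complete_case_filter(t1)
  t3 <- undersample_majority(t2, seed = seed)
  sp <- stratified_split(t3, test_frac = test_frac, seed = seed)
  list(table = t3, split = sp,
       log = data.frame(
         stage = c("input", "missingness_filter", "complete_case", "undersample"),
         rows = c(nrow(table$data), nrow(t1$data), nrow(t2$data), nrow(t3$data)),
         features = c(ncol(table$data), ncol(t1$data), ncol(t2$data), ncol(t3$data))))
}
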