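make_missing_cohort <- function() {
  set.seed(42)
  df <- data.frame(
    keep40 = rnorm(10),
    drop40 = replace(rnorm(10), 1:4, NA),   # 40% missing
    exact30 = replace(rnorm(10), 1:3, NA),  # exactly 30%
    cat1 = factor(rep(c("1", "2"), 5))
  )
  cohort_table(df, rep(c(1, 0), each = 5))
}

test_that("missingness filter drops strictly above the threshold", {
  tbl <- make_missing_cohort()
  out <- drop_high_missingness(tbl, 0.30)
  expect_named(out$data, c("keep40", "exact30", "cat1"))
  # no missing values anywhere -> identity
  full <- complete_case_filter(tbl)
  expect_identical(names(drop_high_missingness(full)$data), names(full$data))
})

test_that("complete-case filter matches a brute-force row scan", {
  tbl <- make_missing_cohort()
  out <- complete_case_filter(tbl)
  expect_equal(nrow(out$data), sum(complete.cases(tbl$data)))
  expect_false(anyNA(out$data))
  # larger synthetic cohort with per-feature missingness
  g <- generate_cohort(planted_cohort_spec(n_cases = 335, n_controls = 3187,
                                           n_features = 10, n_informative = 3,
                                           missing_rate = 0.05, seed = 8))
  cc <- complete_case_filter(g$table)
  manual <- sum(apply(g$table$data, 1, function(r) !anyNA(r)))
  expect_equal(nrow(cc$data), manual)
  # all-missing cohort errors
  allna <- cohort_table(data.frame(a = c(NA_real_, NA_real_)), c(1, 0))
  expect_error(complete_case_filter(allna), "complete")
})

test_that("undersampling balances classes and keeps every minority row", {
  g <- generate_cohort(planted_cohort_spec(n_cases = 335, n_controls = 3187,
                                           n_features = 5, n_informative = 0,
                                           seed = 4))
  bal <- undersample_majority(g$table, seed = 7)
  expect_equal(sum(bal$outcome == 1), 335)
  expect_equal(sum(bal$outcome == 0), 335)
  # minority rows preserved exactly
  expect_equal(bal$data[bal$outcome == 1, ],
               g$table$data[g$table$outcome == 1, ],
               ignore_attr = TRUE)
  # deterministic
  bal2 <- undersample_majority(g$table, seed = 7)
  expect_identical(bal$data, bal2$data)
  # already balanced -> identity
  same <- undersample_majority(bal, seed = 1)
  expect_equal(nrow(same$data), nrow(bal$data))
})

test_that("stratified split hits the per-class rounded test counts", {
  g <- generate_cohort(planted_cohort_spec(n_cases = 335, n_controls = 335,
                                           n_features = 3, n_informative = 0,
                                           seed = 6))
  sp <- stratified_split(g$table, test_frac = 0.20, seed = 2)
  y <- g$table$outcome
  expect_equal(sum(y[sp$test] == 1), 67)
  expect_equal(sum(y[sp$test] == 0), 67)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(stratified_split(g$table, 0.20, seed = 2)$test, sp$test)
  # 0.5 of 4+4 -> 2+2
  small <- cohort_table(data.frame(x = rnorm(8)), rep(c(1, 0), each = 4))
  sp2 <- stratified_split(small, 0.5, seed = 1)
  expect_equal(sum(small$outcome[sp2$test] == 1), 2)
  expect_equal(sum(small$outcome[sp2$test] == 0), 2)
})

test_that("descriptive summary reproduces hand-computed tests", {
  rc <- reference_cohort()
  ds <- descriptive_summary(rc$table)
  # smoking 2x2 from the fixture: chi-squared p < 0.0001
  p_smq <- ds$p_value[ds$feature == "SMQ020"][1]
  expect_lt(p_smq, 1e-4)
  expect_equal(ds$p_formatted[ds$feature == "SMQ020"][1], "<0.0001")
  # identical class-conditional counts -> p = 1
  p_sld <- ds$p_value[ds$feature == "SLD013"][1]
  expect_equal(p_sld, 1)
  # hand-computed chi-squared statistic on the printed smoking counts
  tab <- matrix(c(213, 122, 125, 210), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_hand <- sum((tab - expected)^2 / expected)
  x2_pkg <- suppressWarnings(chisq.test(
    table(rc$table$data$SMQ020, rc$table$outcome)[, c("1", "0")],
    correct = FALSE)$statistic)
  expect_equal(unname(x2_pkg), x2_hand, tolerance = 1e-9)
  expect_equal(p_smq, pchisq(x2_hand, 1, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("identical continuous distributions give a null Wilcoxon result", {
  set.seed(31)
  x <- rnorm(60)
  tbl <- cohort_table(data.frame(v = c(x, x)), rep(c(1, 0), each = 60))
  ds <- descriptive_summary(tbl)
  expect_gt(ds$p_value[ds$feature == "v"], 0.99)
})

test_that("the preparation pipeline is idempotent on its own output", {
  g <- generate_cohort(planted_cohort_spec(n_cases = 100, n_controls = 300,
                                           n_features = 6, n_informative = 2,
                                           missing_rate = 0.05, seed = 13))
  p1 <- prepare_cohort(g$table, seed = 5)
  p2 <- prepare_cohort(p1$table, seed = 5)
  expect_identical(p2$table$data, p1$table$data)
  expect_identical(p2$table$outcome, p1$table$outcome)
})
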