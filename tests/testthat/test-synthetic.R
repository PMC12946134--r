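test_that("generated cohorts have the requested shape and are seed-deterministic", {
  spec <- planted_cohort_spec(n_cases = 335, n_controls = 3187,
                              n_features = 31, n_informative = 5, seed = 11)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_equal(nrow(g1$table$data), 3522)
  expect_equal(ncol(g1$table$data), 31)
  expect_equal(sum(g1$table$outcome == 1), 335)
  expect_identical(g1$table$data, g2$table$data)
  # different seed changes values
  g3 <- generate_cohort(planted_cohort_spec(n_cases = 335, n_controls = 3187,
                                            n_features = 31, seed = 12))
  expect_false(identical(g1$table$data, g3$table$data))
})

test_that("per-feature RNG streams are stable under feature addition", {
  f1 <- feature_spec("a", "continuous", list(dist = "normal", mean = 0, sd = 1))
  f2 <- feature_spec("b", "continuous", list(dist = "normal", mean = 5, sd = 2))
  g_ab <- generate_cohort(cohort_spec(50, 50, list(f1, f2), seed = 3))
  g_a <- generate_cohort(cohort_spec(50, 50, list(f1), seed = 3))
  expect_identical(g_ab$table$data$a, g_a$table$data$a)
})

test_that("non-informative features carry no signal", {
  spec <- planted_cohort_spec(n_cases = 1000, n_controls = 1000,
                              n_features = 10, n_informative = 0, seed = 21)
  g <- generate_cohort(spec)
  expect_length(g$truth$informative_features, 0)
  y <- g$table$outcome
  for (nm in names(g$table$data)) {
    x <- g$table$data[[nm]]
    if (is.numeric(x)) {
      d <- (mean(x[y == 1]) - mean(x[y == 0])) / sd(x[y == 0])
      expect_lt(abs(d), 0.15)
    }
  }
})

test_that("MCAR missingness lands in the central 99% binomial interval", {
  f <- feature_spec("a", "continuous", list(dist = "normal", mean = 0, sd = 1),
                    missing_rate = 0.40)
  g <- generate_cohort(cohort_spec(1000, 1000, list(f), seed = 5))
  nmiss <- sum(is.na(g$table$data$a))
  expect_gte(nmiss, qbinom(0.005, 2000, 0.4))
  expect_lte(nmiss, qbinom(0.995, 2000, 0.4))
})

test_that("categorical features use exact-count allocation", {
  f <- feature_spec("c", "categorical",
                    list(levels = c("1", "2", "3"), probs = c(0.5, 0.3, 0.2)))
  g <- generate_cohort(cohort_spec(100, 200, list(f), seed = 9))
  y <- g$table$outcome
  expect_equal(unname(table(g$table$data$c[y == 1])), c(50, 30, 20),
               ignore_attr = TRUE)
  expect_equal(unname(table(g$table$data$c[y == 0])), c(100, 60, 40),
               ignore_attr = TRUE)
})

test_that("invalid generation parameters raise errors naming the feature", {
  expect_error(feature_spec("badprob", "categorical",
                            list(levels = c("1", "2"), probs = c(0.7, 0.4))),
               "badprob")
  expect_error(feature_spec("badsd", "continuous",
                            list(dist = "normal", mean = 0, sd = -1)),
               "badsd")
})

test_that("planted continuous signal at effect 1.0 is detectable by rank test", {
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    f <- feature_spec("a", "continuous",
                      list(dist = "normal", mean = 1, sd = 1),
                      list(dist = "normal", mean = 0, sd = 1))
    g <- generate_cohort(cohort_spec(500, 500, list(f), seed = 1000 + s))
    y <- g$table$outcome
    p <- wilcox.test(g$table$data$a[y == 1], g$table$data$a[y == 0],
                     exact = FALSE)$p.value
    if (p < 1e-6) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.99)
})

test_that("reference cohort reproduces the published categorical marginals", {
  rc <- reference_cohort()
  tbl <- rc$table
  expect_equal(sum(tbl$outcome == 1), 335)
  expect_equal(sum(tbl$outcome == 0), 335)
  y <- tbl$outcome
  expect_equal(sum(tbl$data$SMQ020 == "1" & y == 1), 213)
  expect_equal(sum(tbl$data$SMQ020 == "1" & y == 0), 125)
  expect_equal(sum(tbl$data$BPQ101D == "1" & y == 1), 242)
  expect_equal(sum(tbl$data$RXQ033 == "2" & y == 0), 108)
  expect_equal(unname(table(tbl$data$DMDEDUC2[y == 1])), c(21, 35, 76, 111, 92),
               ignore_attr = TRUE)
  # deterministic fixture
  expect_identical(tbl$data, reference_cohort()$table$data)
})

test_that("reference cohort continuous medians track the published values", {
  rc <- reference_cohort()
  tbl <- rc$table
  y <- tbl$outcome
  published <- list(  # feature -> c(case median, control median)
    BMXBMI = c(28.90, 28.30), BMXWAIST = c(104.00, 99.60),
    BPXOSY1 = c(127, 117), BPXODI1 = c(74, 76), LBXTC = c(158, 193),
    LBDHDD = c(49, 54), LBXGH = c(5.8, 5.4), LBXHSCRP = c(1.64, 1.92),
    LBXSNASI = c(139, 139), LBXWBCSI = c(6.7, 6.6), LBXHGB = c(13.9, 14.0),
    LBXPLTSI = c(230, 250), LBXRDW = c(13.8, 13.5), PAD800 = c(45, 45),
    PAD680 = c(300, 360)
  )
  for (nm in names(published)) {
    expect_lt(abs(median(tbl$data[[nm]][y == 1]) - published[[nm]][1]) /
                published[[nm]][1], 0.05, label = paste(nm, "case median"))
    expect_lt(abs(median(tbl$data[[nm]][y == 0]) - published[[nm]][2]) /
                published[[nm]][2], 0.05, label = paste(nm, "control median"))
  }
})

test_that("cohort CSV round-trips with empty-string missing values", {
  spec <- planted_cohort_spec(n_cases = 30, n_controls = 30, n_features = 4,
                              n_informative = 2, missing_rate = 0.1, seed = 2)
  g <- generate_cohort(spec)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(g$table, path)
  back <- read_cohort_csv(path, kinds = g$table$kinds)
  expect_equal(back$outcome, g$table$outcome)
  expect_equal(back$data$s01, g$table$data$s01)
  expect_equal(as.character(back$data$s02), as.character(g$table$data$s02))
  gt_path <- tempfile(fileext = ".tsv")
  write_ground_truth(g$truth, gt_path)
  gt <- read.delim(gt_path)
  expect_setequal(gt$feature, g$truth$informative_features)
})
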