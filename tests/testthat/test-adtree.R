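test_that("the rule objective matches hand arithmetic", {
  # partition weights 0.3/0.1 inside the condition, 0.1/0.5 outside
  w <- c(0.3, 0.1, 0.1, 0.5)
  y <- c(1, -1, 1, -1)
  c1 <- rep(TRUE, 4)
  c2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(z_objective(w, y, c1, c2),
               2 * (sqrt(0.03) + sqrt(0.05)), tolerance = 1e-12)
  # perfect split with total weight 1 -> 0
  expect_equal(z_objective(c(0.5, 0.5), c(1, -1), c(TRUE, TRUE),
                           c(TRUE, FALSE)), 0)
  # empty precondition -> total weight survives
  expect_equal(z_objective(w, y, rep(FALSE, 4), c2), sum(w))
})

test_that("a separable toy is fit perfectly with one rule", {
  df <- data.frame(flag = factor(rep(c("1", "2"), each = 4)),
                   noise = c(5, 2, 7, 1, 6, 3, 8, 4))
  y <- c(1, 1, 1, 1, -1, -1, -1, -1)
  m <- adtree(df, y, B = 1)
  expect_length(m$rules, 1)
  expect_equal(m$rules[[1]]$cond$feature, "flag")
  expect_equal(mean(sign(predict(m, df)) == y), 1.0)
})

test_that("B = 0 yields the root-only majority model", {
  df <- data.frame(x = rnorm(10))
  y <- c(rep(1, 7), rep(-1, 3))
  m <- adtree(df, y, B = 0)
  expect_length(m$rules, 0)
  expect_equal(m$root_score, 0.5 * log(0.7 / 0.3), tolerance = 1e-12)
  expect_true(all(predict(m, df, type = "class") == 1))
})

test_that("per-cycle choices match the brute-force oracle on small fixtures", {
  fixtures <- list(
    list(df = toy_cohort()$data, y = ifelse(toy_cohort()$outcome == 1, 1, -1)),
    list(df = data.frame(a = c(1, 2, 3, 4, 5, 6),
                         b = factor(c("u", "v", "u", "v", "u", "v"))),
         y = c(1, 1, -1, 1, -1, -1)),
    list(df = data.frame(a = c(0.1, 0.4, 0.2, 0.9, 0.8, 0.7, 0.3, 0.6),
                         c = c(2, 2, 1, 1, 2, 1, 2, 1)),
         y = c(1, -1, 1, -1, -1, 1, 1, -1))
  )
  for (fx in fixtures) {
    B <- 3
    m <- adtree(fx$df, fx$y, B = B)
    o <- oracle_adtree(fx$df, fx$y, B)
    expect_equal(m$root_score, o$root, tolerance = 1e-12)
    expect_equal(length(m$rules), length(o$choices))
    for (k in seq_along(m$rules)) {
      expect_equal(m$rules[[k]]$cond$feature, o$choices[[k]]$feature)
      expect_equal(m$rules[[k]]$cond$op, o$choices[[k]]$op)
      expect_equal(m$rules[[k]]$cond$value, o$choices[[k]]$value,
                   tolerance = 1e-12)
      expect_equal(m$rules[[k]]$z, o$choices[[k]]$z, tolerance = 1e-12)
      expect_equal(m$rules[[k]]$a, o$choices[[k]]$a, tolerance = 1e-12)
      expect_equal(m$rules[[k]]$b, o$choices[[k]]$b, tolerance = 1e-12)
    }
  }
})

test_that("margins are additive over rules and default to the root", {
  tbl <- toy_cohort()
  y <- ifelse(tbl$outcome == 1, 1, -1)
  m <- adtree(tbl$data, y, B = 3)
  full <- predict(m, tbl$data)
  # removing the last rule changes the margin by exactly its contribution
  m_drop <- m
  last <- m$rules[[length(m$rules)]]
  m_drop$rules <- m$rules[-length(m$rules)]
  reduced <- predict(m_drop, tbl$data)
  pre_ok <- cardiofs:::eval_conj(last$pre, tbl$data)
  cond <- cardiofs:::eval_pred(last$cond, tbl$data)
  contrib <- ifelse(pre_ok, ifelse(cond, last$a, last$b), 0)
  expect_equal(full - reduced, contrib, tolerance = 1e-12)
  # a model with no rules predicts the root everywhere
  m_drop$rules <- list()
  expect_equal(predict(m_drop, tbl$data), rep(m$root_score, 8))
})

test_that("total training weight is non-increasing with epsilon = 0", {
  set.seed(53)
  df <- data.frame(a = rnorm(40), b = rnorm(40),
                   c = factor(sample(c("1", "2", "3"), 40, TRUE)))
  y <- ifelse(df$a + rnorm(40, sd = 1.5) > 0, 1, -1)
  # replay the fit and track the weights through the update rule
  m <- adtree(df, y, B = 6, epsilon = 0)
  w <- rep(1 / 40, 40)
  w <- w * exp(-y * m$root_score)
  totals <- sum(w)
  for (r in m$rules) {
    pre <- cardiofs:::eval_conj(r$pre, df)
    cond <- cardiofs:::eval_pred(r$cond, df)
    w[pre & cond] <- w[pre & cond] * exp(-y[pre & cond] * r$a)
    w[pre & !cond] <- w[pre & !cond] * exp(-y[pre & !cond] * r$b)
    totals <- c(totals, sum(w))
  }
  expect_true(all(diff(totals) <= 1e-12))
})

test_that("features_used reports first-appearance order and matches the oracle", {
  # hand-built model
  m <- structure(list(root_score = 0, B = 3, epsilon = 0.1,
                      rules = list(
                        list(pre = list(), cond = list(feature = "f1", op = "<=", value = 1), a = 1, b = -1),
                        list(pre = list(list(feature = "f1", op = "<=", value = 1)),
                             cond = list(feature = "f3", op = "=", value = "a"), a = 0.5, b = -0.5),
                        list(pre = list(), cond = list(feature = "f1", op = ">", value = 2), a = 0.2, b = -0.2))),
                 class = "adtree")
  expect_equal(features_used(m)$selected, c("f1", "f3"))
  m$rules <- list()
  expect_length(features_used(m)$selected, 0)
  # fitted toy model agrees with the oracle's feature sequence
  tbl <- toy_cohort()
  y <- ifelse(tbl$outcome == 1, 1, -1)
  fit <- adtree(tbl$data, y, B = 3)
  o <- oracle_adtree(tbl$data, y, 3)
  expect_equal(features_used(fit)$selected,
               unique(vapply(o$choices, `[[`, character(1), "feature")))
})

test_that("planted informative features are recovered by the ADT selector", {
  n_seeds <- 15L
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    g <- generate_cohort(recovery_spec(4000 + s))
    m <- adtree(g$table, B = 15)
    used <- features_used(m)$selected
    if (all(g$truth$informative_features %in% used)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("degenerate inputs are rejected or skipped", {
  df <- data.frame(a = rnorm(10), k = rep(1, 10))
  expect_error(adtree(df, rep(1, 10)), "both classes")
  y <- rep(c(1, -1), 5)
  m <- adtree(df, y, B = 2)
  expect_false("k" %in% features_used(m)$selected)
  expect_error(adtree(data.frame(a = c(1, NA)), c(1, -1)), "complete")
})

test_that("serialization round-trips through the text format", {
  tbl <- toy_cohort()
  m <- adtree(tbl$data, ifelse(tbl$outcome == 1, 1, -1), B = 2)
  lines <- format_adtree(m)
  expect_match(lines[1], "^root ")
  expect_length(lines, 1 + length(m$rules))
  path <- tempfile()
  write_adtree(m, path)
  expect_identical(readLines(path), lines)
})
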