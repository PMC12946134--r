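test_that("equal-frequency discretization makes balanced bins", {
  d <- discretize(data.frame(v = 1:100), b = 5)
  expect_equal(unname(table(d$codes$v)), rep(20, 5), ignore_attr = TRUE)
  # constant feature -> single code
  dc <- discretize(data.frame(k = rep(3.3, 50)), b = 5)
  expect_equal(unique(dc$codes$k), 1L)
  # log-normal bins within +/-2 of the ideal occupancy
  set.seed(89)
  x <- rlnorm(1000, 0, 0.8)
  d10 <- discretize(data.frame(x = x), b = 10)
  occ <- table(d10$codes$x)
  expect_true(all(abs(occ - 100) <= 2))
})

test_that("hypergraph construction enumerates feature-value edges", {
  df <- data.frame(a = factor(c("1", "1", "2", "2")),
                   b = factor(c("1", "2", "1", "2")))
  h <- build_hypergraph(discretize(df, 5), c(1, 1, 0, 0))
  expect_equal(length(h$members), 4)
  expect_true(all(lengths(h$members) == 2))
  # per-feature member sets partition the samples
  for (f in c("a", "b")) {
    mem <- unlist(h$members[h$edges$feature == f])
    expect_setequal(mem, 1:4)
  }
  # constant feature -> one full edge
  h2 <- build_hypergraph(discretize(data.frame(k = rep(1, 6)), 5), rep(c(1, 0), 3))
  expect_equal(lengths(h2$members), 6)
  # missing data rejected
  expect_error(build_hypergraph(discretize(data.frame(a = c(1, NA, 3)), 2),
                                c(1, 0, 1)), "complete")
})

test_that("fixture smoking hyperedges have the published sizes", {
  rc <- reference_cohort()
  h <- build_hypergraph(discretize(rc$table, 5), rc$table$outcome)
  sizes <- lengths(h$members)[h$edges$feature == "SMQ020"]
  expect_setequal(sizes, c(338, 332))
})

test_that("walk occupancy matches the closed form and sums to one", {
  rc <- reference_cohort()
  h <- build_hypergraph(discretize(rc$table, 5), rc$table$outcome)
  occ <- random_walk_occupancy(h)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  smq <- which(h$edges$feature == "SMQ020")
  expect_equal(sort(occ[smq]), sort(c(338, 332) / (670 * 31)), tolerance = 1e-12)
  # per-feature occupancies sum to 1/m under complete data
  for (f in unique(h$edges$feature)) {
    expect_equal(sum(occ[h$edges$feature == f]), 1 / 31, tolerance = 1e-12)
  }
  # single feature, single edge -> occupancy 1
  h1 <- build_hypergraph(discretize(data.frame(k = rep(1, 5)), 5), c(1, 1, 0, 0, 0))
  expect_equal(random_walk_occupancy(h1), 1)
})

test_that("edge importance is zero at proportionality and follows hand arithmetic", {
  # balanced 10 samples, 2 features; b's levels each hold equal numbers of
  # cases and controls (exactly proportional to the global 5/5 split)
  df <- data.frame(
    a = factor(c(rep("1", 4), rep("2", 6))),          # edge "1": all class 1
    b = factor(c("1", "1", "2", "2", "2", "1", "1", "2", "2", "2"))
  )
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  h <- build_hypergraph(discretize(df, 5), y)
  imp <- edge_importance(h)
  i_a1 <- which(h$edges$feature == "a" & h$edges$value == 1)
  expect_equal(imp[i_a1], 0.2, tolerance = 1e-12)  # occupancy 4/20 * D=1
  # proportional edge scores exactly zero
  i_b <- which(h$edges$feature == "b")
  expect_equal(imp[i_b], c(0, 0), tolerance = 1e-12)
  # full-vertex edge scores zero
  h2 <- build_hypergraph(discretize(data.frame(k = rep(1, 10), a = df$a), 5), y)
  i_k <- which(h2$edges$feature == "k")
  expect_equal(edge_importance(h2, i_k), 0, tolerance = 1e-12)
})

test_that("feature scores aggregate edges and rank label-copies highest", {
  y <- rep(c(1, 0), each = 5)
  df <- data.frame(lab = factor(y),
                   noise = factor(c("1", "1", "2", "2", "2",
                                    "1", "1", "2", "2", "2")))
  h <- build_hypergraph(discretize(df, 5), y)
  sc <- feature_scores(h)
  expect_equal(unname(sc$feature_score["lab"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(sc$feature_score["noise"]), 0, tolerance = 1e-12)
  expect_equal(sc$ranking[1], "lab")
})

test_that("scores match the eigen-solved first-principles oracle", {
  fixtures <- list(
    list(df = data.frame(a = factor(c("1", "1", "2", "2", "1", "2")),
                         b = c(0.1, 0.3, 0.2, 0.9, 0.8, 0.4)),
         y = c(1, 1, 1, 0, 0, 0)),
    list(df = toy_cohort()$data[1:8, ], y = toy_cohort()$outcome)
  )
  for (fx in fixtures) {
    disc <- discretize(fx$df, b = 3)
    h <- build_hypergraph(disc, fx$y)
    occ <- random_walk_occupancy(h)
    occ_oracle <- oracle_occupancy(h$members, h$n)
    expect_equal(occ, occ_oracle, tolerance = 1e-9)
    sc <- feature_scores(h)
    sc_oracle <- oracle_hfe_scores(h$members, h$edges$feature, fx$y)
    expect_equal(sc$feature_score[names(sc_oracle)],
                 unclass(sc_oracle)[names(sc_oracle)], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("top-beta selection sizes follow round-half-up arithmetic", {
  y <- rep(c(1, 0), each = 20)
  set.seed(97)
  df <- as.data.frame(matrix(rnorm(40 * 31), 40, 31))
  names(df) <- sprintf("f%02d", 1:31)
  sc <- feature_scores(build_hypergraph(discretize(df, 5), y))
  expect_length(select_top_beta(sc, 25)$selected, 8)
  expect_length(select_top_beta(sc, 50)$selected, 16)
  expect_length(select_top_beta(sc, 75)$selected, 23)
})

test_that("label permutation collapses planted feature scores", {
  g <- generate_cohort(planted_cohort_spec(n_cases = 150, n_controls = 150,
                                           n_features = 8, n_informative = 3,
                                           effect = 1.0, seed = 101))
  disc <- discretize(g$table, 5)
  y <- g$table$outcome
  sc0 <- feature_scores(build_hypergraph(disc, y))
  planted <- g$truth$informative_features
  set.seed(103)
  perm_means <- replicate(100, {
    sp <- feature_scores(build_hypergraph(disc, sample(y)))
    mean(sp$feature_score[planted])
  })
  expect_lt(mean(perm_means), mean(sc0$feature_score[planted]))
})
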