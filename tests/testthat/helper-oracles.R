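# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (explicit loops, eigen decompositions,
# permutation enumeration) and share no code with the package internals.

# ---- brute-force alternating decision tree -------------------------------
# Replays the documented fitting procedure with direct mask arithmetic:
# every (path, predicate) candidate is scored by summing weights over
# explicit logical masks. Returns the per-cycle choices.
oracle_adtree <- function(df, y, B, epsilon = 1 / (2 * nrow(df))) {
  n <- nrow(df)
  w <- rep(1 / n, n)
  root <- 0.5 * log(sum(w[y > 0]) / sum(w[y < 0]))
  w <- w * exp(-y * root)
  paths <- list(rep(TRUE, n))
  choices <- list()
  zval <- function(c1, c2) {
    wp1 <- sum(w[c1 & c2 & y > 0]); wm1 <- sum(w[c1 & c2 & y < 0])
    wp2 <- sum(w[c1 & !c2 & y > 0]); wm2 <- sum(w[c1 & !c2 & y < 0])
    2 * (sqrt(wp1 * wm1) + sqrt(wp2 * wm2)) + sum(w[!c1])
  }
  for (cycle in seq_len(B)) {
    best <- NULL; best_z <- Inf
    for (fi in seq_along(df)) {
      x <- df[[fi]]
      for (pi in seq_along(paths)) {
        mask <- paths[[pi]]
        if (!any(mask)) next
        if (is.factor(x)) {
          lv <- levels(droplevels(x[mask]))
          if (length(lv) < 2) next
          for (L in lv) {
            cond <- as.character(x) == L
            z <- zval(mask, cond)
            if (z < best_z - 1e-12) {
              best_z <- z
              best <- list(path = pi, feature = names(df)[fi], op = "=",
                           value = L, cond = cond)
            }
          }
        } else {
          ux <- sort(unique(x[mask]))
          if (length(ux) < 2) next
          for (k in seq_len(length(ux) - 1)) {
            thr <- (ux[k] + ux[k + 1]) / 2
            cond <- x <= thr
            z <- zval(mask, cond)
            if (z < best_z - 1e-12) {
              best_z <- z
              best <- list(path = pi, feature = names(df)[fi], op = "<=",
                           value = thr, cond = cond)
            }
          }
        }
      }
    }
    if (is.null(best) || best_z >= sum(w) - 1e-12) break
    m1 <- paths[[best$path]] & best$cond
    m2 <- paths[[best$path]] & !best$cond
    score <- function(wp, wm) {
      s <- 0.5 * log((wp + epsilon + 1e-300) / (wm + epsilon + 1e-300))
      max(min(s, 50), -50)
    }
    a <- score(sum(w[m1 & y > 0]), sum(w[m1 & y < 0]))
    b <- score(sum(w[m2 & y > 0]), sum(w[m2 & y < 0]))
    choices[[cycle]] <- list(feature = best$feature, op = best$op,
                             value = best$value, z = best_z, a = a, b = b)
    w[m1] <- w[m1] * exp(-y[m1] * a)
    w[m2] <- w[m2] * exp(-y[m2] * b)
    paths <- c(paths, list(m1), list(m2))
  }
  list(root = root, choices = choices)
}

# ---- hypergraph walk solved as an eigenproblem ---------------------------
# States are vertices then hyperedges; the stationary distribution of the
# two-step alternating walk is the leading left eigenvector. Returns edge
# occupancies (stationary mass conditioned on being at an edge).
oracle_occupancy <- function(members, n) {
  E <- length(members)
  P <- matrix(0, n + E, n + E)
  deg <- integer(n)
  for (e in seq_len(E)) deg[members[[e]]] <- deg[members[[e]]] + 1L
  for (e in seq_len(E)) {
    for (v in members[[e]]) {
      P[v, n + e] <- 1 / deg[v]
      P[n + e, v] <- 1 / length(members[[e]])
    }
  }
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi_full <- abs(Re(ev$vectors[, i]))
  pi_edge <- pi_full[n + seq_len(E)]
  pi_edge / sum(pi_edge)
}

# first-principles edge and feature scores from an incidence list
oracle_hfe_scores <- function(members, edge_feature, labels) {
  n <- length(labels)
  occ <- oracle_occupancy(members, n)
  glob <- c(mean(labels == 0), mean(labels == 1))
  imp <- vapply(seq_along(members), function(e) {
    v <- members[[e]]
    inside <- c(mean(labels[v] == 0), mean(labels[v] == 1))
    occ[e] * sum(abs(inside - glob))
  }, numeric(1))
  tapply(imp, edge_feature, sum)
}

# ---- permutation-enumeration Shapley values ------------------------------
# v(S) by direct background averaging; phi by averaging marginal
# contributions over all orderings of the features.
oracle_shapley <- function(f, background, row) {
  feats <- names(background)
  M <- length(feats)
  vfun <- function(S) {
    d <- background
    for (nm in feats[S]) d[[nm]] <- rep(row[[nm]], nrow(background))
    mean(f(d))
  }
  perms <- gtools_permutations(M)
  phi <- numeric(M)
  for (p in seq_len(nrow(perms))) {
    S <- integer(0)
    for (j in perms[p, ]) {
      phi[j] <- phi[j] + (vfun(c(S, j)) - vfun(S)) / nrow(perms)
      S <- c(S, j)
    }
  }
  names(phi) <- feats
  phi
}

# all permutations of 1..n (recursive; n <= 5 in tests)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# ---- small fixture builders ----------------------------------------------

toy_cohort <- function() {
  df <- data.frame(
    age = c(40, 52, 61, 45, 70, 38, 55, 66),
    chol = c(180, 220, 150, 210, 160, 190, 230, 140),
    smoke = factor(c("1", "1", "2", "1", "2", "2", "1", "2"))
  )
  cohort_table(df, c(1, 1, 1, 1, 0, 0, 0, 0))
}

recovery_spec <- function(seed) {
  planted_cohort_spec(n_cases = 300, n_controls = 300, n_features = 20,
                      n_informative = 5, effect = 1.0, tv = 0.3, seed = seed)
}

# single-combination boosting grid used for recovery experiments (skips
# the inner grid search; see the methods vignette)
recovery_grid <- list(max_depth = 3, eta = 0.3, nrounds = 50)
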