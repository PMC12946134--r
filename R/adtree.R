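# Alternating decision tree learner. The model is a root prediction score
# plus an ordered list of rules (precondition, condition predicate, score
# pair). Each boosting cycle adds the rule minimizing the class-separation
# objective
#   Z(c1, c2) = 2 * ( sqrt(W+(c1 & c2)  * W-(c1 & c2))
#                   + sqrt(W+(c1 & !c2) * W-(c1 & !c2)) ) + W(!c1)
# over all (existing tree path, candidate predicate) pairs, where W+/W-
# are class-wise sums of the current boosting weights.

# predicate helpers ---------------------------------------------------------

make_pred <- function(feature, op, value) {
  list(feature = feature, op = op, value = value)
}

negate_pred <- function(p) {
  op <- switch(p$op, "<=" = ">", ">" = "<=", "=" = "!=", "!=" = "=")
  make_pred(p$feature, op, p$value)
}

eval_pred <- function(p, df) {
  x <- df[[p$feature]]
  if (is.null(x)) stopf("row is missing feature '%s'", p$feature)
  switch(p$op,
         "<=" = as.numeric(x) <= p$value,
         ">"  = as.numeric(x) >  p$value,
         "="  = as.character(x) == as.character(p$value),
         "!=" = as.character(x) != as.character(p$value))
}

eval_conj <- function(preds, df) {
  out <- rep(TRUE, nrow(df))
  for (p in preds) out <- out & eval_pred(p, df)
  out
}

format_pred <- function(p) {
  sprintf("%s %s %s", p$feature, if (p$op == "=") "==" else p$op,
          format(p$value, digits = 10))
}

# objective -----------------------------------------------------------------

#' ADT rule objective
#'
#' The boosting criterion minimized when adding a rule: small when the
#' candidate condition splits the precondition region into class-pure
#' parts, and equal to the total weight when the precondition covers
#' nothing.
#'
#' @param weights positive per-row boosting weights.
#' @param labels class labels in \{-1, +1\}.
#' @param c1 logical vector: rows satisfying the precondition.
#' @param c2 logical vector: rows satisfying the candidate condition.
#' @return the scalar objective value.
#' @export
z_objective <- function(weights, labels, c1, c2) {
  stopifnot(length(weights) == length(labels),
            length(c1) == length(weights), length(c2) == length(weights))
  pos <- labels > 0
  wp1 <- sum(weights[c1 & c2 & pos]);  wm1 <- sum(weights[c1 & c2 & !pos])
  wp2 <- sum(weights[c1 & !c2 & pos]); wm2 <- sum(weights[c1 & !c2 & !pos])
  2 * (sqrt(wp1 * wm1) + sqrt(wp2 * wm2)) + sum(weights[!c1])
}

# smoothed log-odds rule score, kept finite even at epsilon = 0 on pure
# partitions (clamped below the optimum, which preserves the weight
# monotonicity of the boosting update)
rule_score <- function(wp, wm, epsilon) {
  s <- 0.5 * log((wp + epsilon + 1e-300) / (wm + epsilon + 1e-300))
  max(min(s, 50), -50)
}

# fitting -------------------------------------------------------------------

#' Fit an alternating decision tree
#'
#' Boosted rule learner over a complete-case mixed-type table. Training
#' weights start uniform at 1/t; the root prediction score is
#' `0.5 * log(W+ / W-)` at those weights and is applied as a weight
#' update before the first cycle. Each cycle scans every (tree path,
#' candidate predicate) pair — candidate thresholds for continuous
#' features are midpoints between consecutive sorted distinct values in
#' the path's region, and categorical candidates test equality to each
#' observed level — and adds the rule minimizing the Z objective. Rule
#' scores are smoothed log-odds `0.5 * log((W+ + eps) / (W- + eps))` on
#' each side of the condition; weights are then multiplied by
#' `exp(-y * score)` on the rows the rule touches. Fitting stops after
#' `B` cycles or as soon as no candidate improves on the current total
#' weight. Ties in Z are broken toward the earliest feature in column
#' order, then the earliest-created path, then the smallest threshold.
#'
#' @param x a [cohort_table()], or a data.frame of features.
#' @param y class labels (ignored when `x` is a `cohort_table`): 0/1 or
#'   -1/+1; 1 is the positive class.
#' @param B maximum number of boosting cycles (rules).
#' @param epsilon score smoothing constant; default `1 / (2t)`.
#' @return an object of class `adtree`: `root_score`, `rules` (each with
#'   `pre`, `cond`, `a`, `b`, `z`), `B`, `epsilon`, `features`.
#' @export
adtree <- function(x, y = NULL, B = 50, epsilon = NULL) {
  if (inherits(x, "cohort_table")) {
    y <- ifelse(x$outcome == 1, 1, -1)
    df <- x$data
  } else {
    df <- as.data.frame(x)
    if (is.null(y)) stopf("y is required when x is not a cohort_table")
    y <- as.numeric(y)
    if (all(y %in% c(0, 1))) y <- ifelse(y == 1, 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stopf("labels must be binary")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  if (anyNA(df)) stopf("adtree requires a complete-case table")
  n <- nrow(df)
  if (is.null(epsilon)) epsilon <- 1 / (2 * n)

  w <- rep(1 / n, n)
  pos <- y > 0
  root <- 0.5 * log(sum(w[pos]) / sum(w[!pos]))
  w <- w * exp(-y * root)

  is_cat <- vapply(df, is.factor, logical(1))
  num_cols <- lapply(df, function(col) if (is.factor(col)) NULL else as.numeric(col))
  ord_cols <- lapply(num_cols, function(v) if (is.null(v)) NULL else order(v))

  paths <- list(list(preds = list(), mask = rep(TRUE, n)))
  rules <- list()

  for (cycle in seq_len(max(B, 0))) {
    wtot <- sum(w)
    wp <- w * pos
    wm <- w * (!pos)
    best <- list(z = Inf)
    for (fi in seq_along(df)) {
      f <- names(df)[fi]
      for (pi in seq_along(paths)) {
        mask <- paths[[pi]]$mask
        win <- sum(w[mask])
        if (win <= 0) next
        wout <- wtot - win
        if (is_cat[fi]) {
          xv <- df[[fi]][mask]
          lv <- levels(droplevels(xv))
          if (length(lv) < 2) next  # constant within this region
          for (L in lv) {
            inl <- xv == L
            wp1 <- sum(wp[mask][inl]); wm1 <- sum(wm[mask][inl])
            wp2 <- sum(wp[mask][!inl]); wm2 <- sum(wm[mask][!inl])
            z <- 2 * (sqrt(wp1 * wm1) + sqrt(wp2 * wm2)) + wout
            if (z < best$z - 1e-12) {
              best <- list(z = z, path = pi, pred = make_pred(f, "=", L))
            }
          }
        } else {
          o <- ord_cols[[fi]]
          rows <- o[mask[o]]
          if (length(rows) < 2) next
          xs <- num_cols[[fi]][rows]
          nb <- length(xs)
          cwp <- cumsum(wp[rows]); cwm <- cumsum(wm[rows])
          bnd <- which(xs[-nb] < xs[-1])
          if (!length(bnd)) next
          WpT <- cwp[nb]; WmT <- cwm[nb]
          z <- 2 * (sqrt(cwp[bnd] * cwm[bnd]) +
                    sqrt(pmax(WpT - cwp[bnd], 0) * pmax(WmT - cwm[bnd], 0))) +
               wout
          k <- which(z <= min(z) + 1e-12)[1]  # smallest threshold on ties
          if (z[k] < best$z - 1e-12) {
            thr <- (xs[bnd[k]] + xs[bnd[k] + 1]) / 2
            best <- list(z = z[k], path = pi, pred = make_pred(f, "<=", thr))
          }
        }
      }
    }
    if (!is.finite(best$z) || best$z >= wtot - 1e-12) break

    pre <- paths[[best$path]]
    cond <- eval_pred(best$pred, df)
    m1 <- pre$mask & cond
    m2 <- pre$mask & !cond
    a <- rule_score(sum(w[m1 & pos]), sum(w[m1 & !pos]), epsilon)
    b <- rule_score(sum(w[m2 & pos]), sum(w[m2 & !pos]), epsilon)
    rules[[length(rules) + 1]] <- list(pre = pre$preds, cond = best$pred,
                                       a = a, b = b, z = best$z)
    w[m1] <- w[m1] * exp(-y[m1] * a)
    w[m2] <- w[m2] * exp(-y[m2] * b)
    paths[[length(paths) + 1]] <- list(preds = c(pre$preds, list(best$pred)),
                                       mask = m1)
    paths[[length(paths) + 1]] <- list(preds = c(pre$preds,
                                                 list(negate_pred(best$pred))),
                                       mask = m2)
  }

  structure(list(root_score = root, rules = rules, B = B, epsilon = epsilon,
                 features = names(df),
                 kinds = ifelse(is_cat, "categorical", "continuous")),
            class = "adtree")
}

#' Prediction margins of an alternating decision tree
#'
#' The margin of a row is the root score plus, for every rule whose
#' precondition the row satisfies, the rule's true-score if the condition
#' holds and its false-score otherwise. The predicted class is the sign
#' of the margin.
#'
#' @param object a fitted [adtree()].
#' @param newdata data.frame (or [cohort_table()]) of rows providing all
#'   features the model references.
#' @param type `"margin"` (default) or `"class"` (-1/+1).
#' @param ... unused.
#' @return numeric margins or class labels.
#' @export
predict.adtree <- function(object, newdata, type = c("margin", "class"), ...) {
  type <- match.arg(type)
  df <- if (inherits(newdata, "cohort_table")) newdata$data else as.data.frame(newdata)
  m <- rep(object$root_score, nrow(df))
  for (r in object$rules) {
    ok <- eval_conj(r$pre, df)
    cond <- eval_pred(r$cond, df)
    m[ok & cond] <- m[ok & cond] + r$a
    m[ok & !cond] <- m[ok & !cond] + r$b
  }
  if (type == "class") ifelse(m >= 0, 1, -1) else m
}

#' Features referenced by a fitted ADT
#'
#' @param model a fitted [adtree()].
#' @return a [selection_result()]: feature names appearing in any rule's
#'   precondition or condition, ordered by first appearance.
#' @export
features_used <- function(model) {
  stopifnot(inherits(model, "adtree"))
  seen <- character(0)
  for (r in model$rules) {
    for (p in c(r$pre, list(r$cond))) {
      if (!p$feature %in% seen) seen <- c(seen, p$feature)
    }
  }
  selection_result("adtree", list(B = model$B), seen)
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("adtree: root score %.4f, %d rule(s) (B = %d, epsilon = %g)\n",
              x$root_score, length(x$rules), x$B, x$epsilon))
  invisible(x)
}

#' @export
summary.adtree <- function(object, ...) {
  cat(format_adtree(object), sep = "\n")
  invisible(object)
}

#' Text serialization of an ADT
#'
#' Deterministic line-based format (one line per rule) suitable for
#' diffing.
#' @param model a fitted [adtree()].
#' @return character vector of lines.
#' @export
format_adtree <- function(model) {
  lines <- sprintf("root %.10g", model$root_score)
  for (i in seq_along(model$rules)) {
    r <- model$rules[[i]]
    pre <- if (length(r$pre)) paste(vapply(r$pre, format_pred, character(1)),
                                    collapse = " & ") else "true"
    lines <- c(lines, sprintf("rule %d | pre: %s | cond: %s | a=%.10g b=%.10g",
                              i, pre, format_pred(r$cond), r$a, r$b))
  }
  lines
}

#' @rdname format_adtree
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_adtree <- function(model, path) {
  writeLines(format_adtree(model), path)
  invisible(path)
}
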