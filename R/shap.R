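# Shapley-value attributions for probability-outputting classifiers.
# Coalition values are background expectations: v(S) is the mean model
# output over the background rows with the features in S fixed to the
# explained sample's values. With few features the Shapley values are
# computed by exact coalition enumeration (local accuracy holds to
# machine precision); otherwise by the kernel-weighted linear regression
# approximation with the sum-to-output constraint enforced exactly.

# hybrid frame: columns in `on` come from `row`, others from `background`
hybrid_frame <- function(row, background, on) {
  out <- background
  for (nm in on) out[[nm]] <- rep(row[[nm]], nrow(background))
  out
}

shap_weight <- function(s, M) {
  exp(lfactorial(s) + lfactorial(M - s - 1) - lfactorial(M))
}

#' Shapley-value attributions
#'
#' @param model fitted model accepted by [predict_prob()], or a function
#'   `f(data.frame) -> numeric` returning the model output directly.
#' @param background data.frame of background rows defining the reference
#'   distribution (kept small; every coalition evaluation averages over
#'   all of it).
#' @param samples data.frame of rows to explain.
#' @param exact_limit exact enumeration is used when the feature count is
#'   at most this (default 10); above it the kernel regression
#'   approximation is used.
#' @param n_coalitions number of sampled coalitions for the kernel
#'   regression (in addition to all size-1 and size-(M-1) coalitions).
#' @param seed seed for coalition sampling.
#' @return a `shap_attribution`: `phi` (samples x features matrix),
#'   `base_value` (mean model output on the background), `fx` (model
#'   output per sample), `residual` (local-accuracy residual per
#'   sample), `method`.
#' @export
shap_explain <- function(model, background, samples, exact_limit = 10L,
                         n_coalitions = 1000L, seed = 1L) {
  f <- if (is.function(model)) model else function(d) predict_prob(model, d)
  background <- as.data.frame(background)
  samples <- as.data.frame(samples)
  if (nrow(background) == 0) stopf("background must be nonempty")
  feats <- names(background)
  samples <- samples[, feats, drop = FALSE]
  M <- length(feats)
  exact <- M <= exact_limit
  phi <- matrix(0, nrow(samples), M, dimnames = list(NULL, feats))
  base <- mean(f(background))
  fx <- numeric(nrow(samples))

  if (exact) {
    nS <- 2^M
    masks <- lapply(seq_len(nS) - 1L, function(s)
      which(bitwAnd(s, bitwShiftL(1L, seq_len(M) - 1L)) > 0L))
    sizes <- lengths(masks)
    wts <- shap_weight(sizes, M)  # weight of S as the "without-j" set
    for (i in seq_len(nrow(samples))) {
      row <- samples[i, , drop = FALSE]
      v <- vapply(masks, function(s)
        mean(f(hybrid_frame(row, background, feats[s]))), numeric(1))
      fx[i] <- v[nS]  # full coalition: all features from the sample
      for (j in seq_len(M)) {
        bit <- bitwShiftL(1L, j - 1L)
        without <- which(bitwAnd(seq_len(nS) - 1L, bit) == 0L)
        with <- without + bit / 1L
        phi[i, j] <- sum(wts[without] * (v[with] - v[without]))
      }
    }
  } else {
    set.seed(derive_seed(seed, "kernel_shap"))
    if (M <= 25 && 2^M - 2 <= max(n_coalitions, 2 * M)) {
      # all proper nonempty coalitions with exact kernel weights: the
      # weighted regression then recovers the Shapley values exactly
      coal <- lapply(seq_len(2^M - 2), function(s)
        which(bitwAnd(s, bitwShiftL(1L, seq_len(M) - 1L)) > 0L))
    } else {
      # fixed coalitions: every singleton and every complement-singleton
      coal <- c(lapply(seq_len(M), function(j) j),
                lapply(seq_len(M), function(j) setdiff(seq_len(M), j)))
      ssizes <- 2:(M - 2)
      if (length(ssizes) && n_coalitions > 0) {
        pr <- (M - 1) / (ssizes * (M - ssizes))
        draw_s <- sample(ssizes, n_coalitions, replace = TRUE, prob = pr)
        coal <- c(coal, lapply(draw_s, function(s) sort(sample.int(M, s))))
      }
    }
    coal <- coal[!duplicated(vapply(coal, paste, character(1), collapse = ","))]
    Z <- t(vapply(coal, function(s) {
      z <- numeric(M); z[s] <- 1; z
    }, numeric(M)))
    sz <- rowSums(Z)
    kw <- (M - 1) / (choose(M, sz) * sz * (M - sz))
    for (i in seq_len(nrow(samples))) {
      row <- samples[i, , drop = FALSE]
      v <- vapply(coal, function(s)
        mean(f(hybrid_frame(row, background, feats[s]))), numeric(1))
      fx[i] <- f(row)
      delta <- fx[i] - base
      # eliminate phi_M via the sum constraint, weighted least squares
      yk <- v - base - Z[, M] * delta
      X <- Z[, -M, drop = FALSE] - Z[, M]
      fit <- stats::lm.wfit(X, yk, kw)
      ph <- fit$coefficients
      ph[is.na(ph)] <- 0
      phi[i, -M] <- ph
      phi[i, M] <- delta - sum(ph)
    }
  }
  structure(list(phi = phi, base_value = base, fx = fx,
                 residual = base + rowSums(phi) - fx,
                 method = if (exact) "exact" else "kernel"),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("shap_attribution (%s): %d sample(s) x %d feature(s), base value %.4f\n",
              x$method, nrow(x$phi), ncol(x$phi), x$base_value))
  cat(sprintf("  max |local accuracy residual| = %.3g\n", max(abs(x$residual))))
  invisible(x)
}

#' Summarize attributions across samples
#'
#' Features are ranked by mean absolute attribution. For categorical
#' features the attribution values are grouped by observed level; for
#' continuous features the (value, attribution) pairs are returned for
#' direction plots.
#'
#' @param attr a `shap_attribution`.
#' @param data the explained samples (same rows as `attr$phi`); needed
#'   for the per-level / per-value views. Optional.
#' @param kinds optional named kind vector (`"continuous"`/
#'   `"categorical"`); inferred from `data` column types if missing.
#' @return an `attribution_summary`: `ranking` (data.frame feature,
#'   mean_abs), `by_level` (named list of data.frames level/attribution),
#'   `by_value` (named list of data.frames value/attribution).
#' @export
attribution_summary <- function(attr, data = NULL, kinds = NULL) {
  stopifnot(inherits(attr, "shap_attribution"))
  if (nrow(attr$phi) == 0) stopf("empty attribution matrix")
  ma <- colMeans(abs(attr$phi))
  ord <- order(-ma, seq_along(ma))
  ranking <- data.frame(feature = colnames(attr$phi)[ord],
                        mean_abs = unname(ma[ord]))
  by_level <- list(); by_value <- list()
  if (!is.null(data)) {
    data <- as.data.frame(data)
    if (is.null(kinds))
      kinds <- vapply(data, function(c) if (is.factor(c) || is.character(c))
        "categorical" else "continuous", character(1))
    for (nm in colnames(attr$phi)) {
      if (!nm %in% names(data)) next
      if (identical(kinds[[nm]], "categorical")) {
        by_level[[nm]] <- data.frame(level = as.character(data[[nm]]),
                                     attribution = attr$phi[, nm])
      } else {
        by_value[[nm]] <- data.frame(value = as.numeric(data[[nm]]),
                                     attribution = attr$phi[, nm])
      }
    }
  }
  structure(list(ranking = ranking, by_level = by_level, by_value = by_value),
            class = "attribution_summary")
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat("attribution_summary (mean |attribution| per feature):\n")
  print(utils::head(x$ranking, 15), row.names = FALSE)
  invisible(x)
}

#' Bar plot of mean absolute attributions
#' @param x an `attribution_summary`.
#' @param top number of features to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.attribution_summary <- function(x, top = 15, ...) {
  r <- utils::head(x$ranking, top)
  graphics::barplot(rev(r$mean_abs), names.arg = rev(r$feature), horiz = TRUE,
                    las = 1, xlab = "mean |attribution|", ...)
  invisible(x)
}
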