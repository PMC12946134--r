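# internal helpers shared across modules

# round-half-up: round(0.5) in R is banker's rounding, selection-size
# arithmetic needs 7.75 -> 8, 15.5 -> 16, 23.25 -> 23
round_half_up <- function(x) floor(x + 0.5)

# deterministic 31-bit stream seed from (seed, name) so per-feature RNG
# streams are independent of feature order
derive_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(as.character(name))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# p-value display used by the descriptive table: 4 decimals, "<0.0001" floor
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001", formatC(p, digits = 4, format = "f")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# stratified fold assignment: per-class shuffled round-robin
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# numeric design matrix for the classifiers: factors -> integer level codes
# (NHANES variables are numerically coded; tree/kernel models see the codes)
as_numeric_matrix <- function(df) {
  m <- vapply(df, function(col) {
    if (is.factor(col)) {
      v <- suppressWarnings(as.numeric(as.character(col)))
      if (anyNA(v) && !all(is.na(col) == is.na(v))) v <- as.numeric(col)  # non-numeric labels
      v
    } else {
      as.numeric(col)
    }
  }, numeric(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  colnames(m) <- names(df)
  m
}
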