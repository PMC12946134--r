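#' Construct a selection result
#'
#' Common return type of all four feature-selection strategies: the
#' ordered surviving feature names, optional per-feature scores, and an
#' audit trail of removals.
#'
#' @param method method name.
#' @param params named list of the parameters the method ran with.
#' @param selected character vector of retained feature names (ordered).
#' @param scores optional named numeric vector of feature scores.
#' @param audit data.frame of removals: columns `feature`, `reason`,
#'   `partner`, `statistic`, `p_value` (columns may be NA where not
#'   applicable).
#' @return a `selection_result` object.
#' @export
selection_result <- function(method, params, selected, scores = NULL,
                             audit = NULL) {
  if (is.null(audit))
    audit <- data.frame(feature = character(0), reason = character(0),
                        partner = character(0), statistic = numeric(0),
                        p_value = numeric(0), stringsAsFactors = FALSE)
  structure(list(method = method, params = params, selected = selected,
                 scores = scores, audit = audit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  pstr <- paste(names(x$params), unlist(lapply(x$params, format)),
                sep = "=", collapse = ", ")
  cat(sprintf("selection_result [%s%s]: %d feature(s) selected, %d removed\n",
              x$method, if (nzchar(pstr)) paste0(" (", pstr, ")") else "",
              length(x$selected), nrow(x$audit)))
  cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a selection audit CSV
#' @param result a `selection_result`.
#' @param path output CSV path.
#' @param candidates optional full candidate list, so kept features appear
#'   in the audit too.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(result, path, candidates = NULL) {
  aud <- result$audit
  if (!is.null(candidates)) {
    kept <- data.frame(feature = setdiff(candidates, aud$feature),
                       reason = "kept", partner = NA_character_,
                       statistic = NA_real_, p_value = NA_real_,
                       stringsAsFactors = FALSE)
    aud <- rbind(kept, aud)
  }
  aud$status <- ifelse(aud$reason == "kept", "kept", "removed")
  utils::write.csv(aud, path, row.names = FALSE)
  invisible(path)
}
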