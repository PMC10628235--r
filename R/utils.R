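# Shared helpers: label normalization, seed splitting, input checks.

#' Normalize taxon labels for matching
#'
#' Trims surrounding whitespace, converts underscores to spaces (the Newick
#' convention) and collapses runs of internal whitespace, so that
#' `"Thescelosaurus_neglectus"` and `" Thescelosaurus  neglectus "` match.
#' Original labels are never rewritten; normalization is used only when
#' matching trait tables against tree tips.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_taxon("Thescelosaurus_neglectus")
normalize_taxon <- function(x) {
  x <- gsub("_", " ", as.character(x), fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Deterministic sub-seed derivation so one user seed can drive several
# independent draws. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + 11 * as.numeric(index) + 1
  as.integer(s %% m)
}

check_positive <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (!is.finite(x) | x <= 0) else
    (is.na(x) | !is.finite(x) | x <= 0)
  if (any(bad)) {
    abort(sprintf("`%s` must be positive and finite (offending values: %s).",
                  name, paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (any(is.na(x) | x <= 0 | x > 1)) {
    abort(sprintf("`%s` must lie in (0, 1].", name))
  }
  invisible(x)
}

# Column presence check with a readable error.
check_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Input data is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  invisible(data)
}
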