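#' Deterministic half-up rounding
#'
#' Rounds away from zero on ties (0.125 -> 0.13 at 2 digits), unlike
#' [base::round()]'s round-half-even. Used for all displayed percentages so
#' results are stable across platforms. A small epsilon guards against
#' binary-representation ties landing just below .5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 54 / 786, 2)  # 6.87
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Normalize a drug name
#'
#' Lowercases, trims and collapses internal whitespace, then applies an
#' optional exact-match synonym map (e.g. to strip salt descriptors:
#' `c("sildenafil citrate" = "sildenafil")`). No fuzzy matching.
#'
#' @param x character vector of raw drug names.
#' @param synonyms named character vector mapping normalized variants to the
#'   canonical name; applied after lowercasing/trimming.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x, synonyms = NULL) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  if (!is.null(synonyms) && length(synonyms)) {
    names(synonyms) <- normalize_drug_name(names(synonyms))
    hit <- match(x, names(synonyms))
    x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# percentage of n out of total, half-up to 2 decimals; NA for empty cohorts
pct2 <- function(n, total) {
  if (total <= 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / total, 2)
}
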