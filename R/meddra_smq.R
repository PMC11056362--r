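#' Construct an SMQ definition
#'
#' A Standardized MedDRA Query (SMQ) is a curated set of preferred terms
#' (PTs) defining a medical condition of interest. Members are (term, code)
#' pairs; codes are 8-digit MedDRA PT codes and must be unique within the
#' definition.
#'
#' @param name query name.
#' @param members data frame with columns `term` and `code`.
#' @param scope `"narrow"` (highly specific terms only) or `"broad"`.
#' @return an object of class `smq_definition`.
#' @export
smq_definition <- function(name, members, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  members <- as.data.frame(members)
  if (!all(c("term", "code") %in% names(members))) {
    stop("members must have columns 'term' and 'code'", call. = FALSE)
  }
  members$term <- as.character(members$term)
  members$code <- as.integer(members$code)
  if (nrow(members) == 0) stop("SMQ must have at least one member PT",
                               call. = FALSE)
  if (any(is.na(members$term) | !nzchar(members$term))) {
    stop("SMQ member with empty term", call. = FALSE)
  }
  dup <- members$code[duplicated(members$code)]
  if (length(dup)) {
    stop("duplicate PT code(s) in SMQ: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  rownames(members) <- NULL
  structure(list(name = name, scope = scope,
                 members = members[, c("term", "code")]),
            class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("<smq_definition> %s (%s scope), %d PTs\n",
              x$name, x$scope, nrow(x$members)))
  invisible(x)
}

#' Load an SMQ definition from a two-column delimited file
#'
#' The file has a header row and columns `term` and `code` (tab- or
#' comma-delimited, detected from the header). Codes must be 8-digit
#' numbers; a malformed code is fatal and reported with its line number.
#'
#' @param path file path.
#' @param name query name; defaults to the file name.
#' @param scope `"narrow"` or `"broad"`.
#' @return an `smq_definition`.
#' @export
load_smq <- function(path, name = NULL, scope = "narrow") {
  if (!file.exists(path)) stop("SMQ file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("term", "code") %in% names(df))) {
    stop("SMQ file must have 'term' and 'code' columns: ", path,
         call. = FALSE)
  }
  bad <- !grepl("^[0-9]{8}$", trimws(df$code))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed PT code '%s' at line %d of %s",
                 df$code[i], i + 1L, path), call. = FALSE)
  }
  smq_definition(name %||% sub("\\.[^.]*$", "", basename(path)),
                 data.frame(term = trimws(df$term),
                            code = as.integer(trimws(df$code)),
                            stringsAsFactors = FALSE),
                 scope = scope)
}

#' The packaged narrow SMQ for hearing impairment
#'
#' Loads the 56-term narrow-scope hearing-impairment SMQ shipped with the
#' package (PTs such as Tinnitus 10043882, Hypoacusis 10048865, Sudden
#' hearing loss 10061373).
#'
#' @return an `smq_definition` with 56 member PTs.
#' @export
hearing_impairment_smq <- function() {
  path <- system.file("extdata", "smq_hearing_impairment_narrow.tsv",
                      package = "pvsignal", mustWork = TRUE)
  load_smq(path, name = "hearing impairment", scope = "narrow")
}

#' Does a report's reaction set intersect an SMQ?
#'
#' Matching is by numeric PT code when a code is present, falling back to
#' case-insensitive exact term match for term-only rows; no substring or
#' fuzzy matching.
#'
#' @param pt_codes integer vector of the report's reaction PT codes (`NA`
#'   allowed for term-only reactions).
#' @param smq an `smq_definition`.
#' @param pt_terms optional character vector of terms, parallel to
#'   `pt_codes`, used for rows whose code is `NA`.
#' @return `TRUE` iff at least one reaction belongs to the SMQ.
#' @export
report_matches_smq <- function(pt_codes, smq, pt_terms = NULL) {
  if (any(pt_codes %in% smq$members$code)) return(TRUE)
  if (!is.null(pt_terms)) {
    t_only <- is.na(pt_codes) & !is.na(pt_terms)
    if (any(tolower(pt_terms[t_only]) %in% tolower(smq$members$term))) {
      return(TRUE)
    }
  }
  FALSE
}

# report ids in the collection with >= 1 reaction in the SMQ (report-level)
smq_report_ids <- function(x, smq) {
  r <- x$reactions
  hit <- r$pt_code %in% smq$members$code |
    (is.na(r$pt_code) & tolower(r$pt_term) %in% tolower(smq$members$term))
  unique(r$report_id[hit])
}

#' Per-PT report counts for a drug under an SMQ
#'
#' For each member PT of the query, counts the primary-suspect reports for
#' `drug_name` that mention that PT. The counting unit is the report: a
#' report with two member PTs contributes once to each PT's count (so the
#' column sum can exceed the SMQ-level report count). Sorted by descending
#' count, ties broken alphabetically by term. With `apply_min_n = TRUE`
#' (the usual sparse-cell reporting convention), PTs with fewer than
#' `min_n` reports are excluded.
#'
#' @param x a deduplicated `report_collection`.
#' @param drug_name drug of interest.
#' @param smq an `smq_definition`.
#' @param min_n minimum report count; default 3.
#' @param apply_min_n apply the filter?
#' @return data frame with columns `term`, `code`, `n`.
#' @export
pt_breakdown <- function(x, drug_name, smq, min_n = 3, apply_min_n = TRUE) {
  ps <- primary_suspect_ids(x, drug_name)
  r <- x$reactions[x$reactions$report_id %in% ps, , drop = FALSE]
  # map each reaction row to a member PT (code first, then exact term)
  idx <- match(r$pt_code, smq$members$code)
  t_idx <- match(tolower(r$pt_term), tolower(smq$members$term))
  idx[is.na(r$pt_code)] <- t_idx[is.na(r$pt_code)]
  r <- r[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (nrow(r) == 0) {
    return(data.frame(term = character(), code = integer(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  # one count per (report, member PT)
  key <- unique(data.frame(report_id = r$report_id, member = idx,
                           stringsAsFactors = FALSE))
  cnt <- table(factor(key$member, levels = seq_len(nrow(smq$members))))
  out <- data.frame(term = smq$members$term, code = smq$members$code,
                    n = as.integer(cnt), stringsAsFactors = FALSE)
  out <- out[out$n > 0, , drop = FALSE]
  if (apply_min_n) out <- out[out$n >= min_n, , drop = FALSE]
  out <- out[order(-out$n, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
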