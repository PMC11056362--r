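#' @name report_collection
#' @title An in-memory collection of spontaneous safety reports
#'
#' @description
#' The central container of the package. A `report_collection` mirrors the
#' FAERS quarterly split into four relational tables joined on `report_id`:
#'
#' * `demo` -- one row per report: `report_id`, `case_id` (the duplicate
#'   grouping key, i.e. the case/ISR number), `age` (years, `NA` = unknown),
#'   `sex` (`"male"`, `"female"`, `"unknown"`), `country` (`NA` = unknown),
#'   `year` (reporting year).
#' * `drugs` -- one row per drug entry: `report_id`, `drug_name` (normalized),
#'   `role` (`"primary_suspect"`, `"secondary_suspect"`, `"concomitant"`,
#'   `"interacting"`), `dose_text`, `indication_pt` (both optional, `NA`).
#' * `reactions` -- one row per reaction: `report_id`, `pt_code` (8-digit
#'   MedDRA preferred-term code, `NA` when only a term is given), `pt_term`.
#' * `outcomes` -- zero or more rows per report: `report_id`, `outcome`
#'   (`"hospitalization"`, `"disability"`, `"life_threatening"`, `"death"`,
#'   `"required_intervention"`, `"other"`).
#'
#' Invariants enforced by the constructor: `report_id` unique; every report
#' has at least one drug entry and at least one reaction; known ages lie in
#' [0, 120]; roles and outcomes come from their enumerations.
#'
#' @param demo,drugs,reactions,outcomes data frames as described above.
#' @param provenance free-text description of where the data came from.
#' @param log character vector of load/generation log lines.
#' @return an object of class `report_collection`.
#' @export
report_collection <- function(demo, drugs, reactions,
                              outcomes = NULL, provenance = "",
                              log = character()) {
  demo <- as.data.frame(demo)
  drugs <- as.data.frame(drugs)
  reactions <- as.data.frame(reactions)
  if (is.null(outcomes)) {
    outcomes <- data.frame(report_id = character(), outcome = character(),
                           stringsAsFactors = FALSE)
  }
  outcomes <- as.data.frame(outcomes)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(demo, c("report_id", "case_id", "age", "sex", "country", "year"), "demo")
  need(drugs, c("report_id", "drug_name", "role"), "drugs")
  need(reactions, c("report_id", "pt_code", "pt_term"), "reactions")
  need(outcomes, c("report_id", "outcome"), "outcomes")
  if (!"dose_text" %in% names(drugs)) drugs$dose_text <- NA_character_
  if (!"indication_pt" %in% names(drugs)) drugs$indication_pt <- NA_character_

  demo$report_id <- as.character(demo$report_id)
  demo$case_id <- as.character(demo$case_id)
  demo$age <- as.numeric(demo$age)
  demo$sex <- as.character(demo$sex)
  demo$country <- as.character(demo$country)
  demo$year <- as.integer(demo$year)
  drugs$report_id <- as.character(drugs$report_id)
  drugs$drug_name <- as.character(drugs$drug_name)
  drugs$role <- as.character(drugs$role)
  reactions$report_id <- as.character(reactions$report_id)
  reactions$pt_code <- as.integer(reactions$pt_code)
  reactions$pt_term <- as.character(reactions$pt_term)
  outcomes$report_id <- as.character(outcomes$report_id)
  outcomes$outcome <- as.character(outcomes$outcome)

  if (anyDuplicated(demo$report_id)) {
    stop("duplicate report_id in demo table", call. = FALSE)
  }
  bad_age <- !is.na(demo$age) & (demo$age < 0 | demo$age > 120)
  if (any(bad_age)) {
    stop("age outside [0, 120] for report(s): ",
         paste(demo$report_id[bad_age], collapse = ", "), call. = FALSE)
  }
  if (!all(demo$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be one of male/female/unknown", call. = FALSE)
  }
  if (!all(drugs$role %in% drug_roles())) {
    stop("invalid drug role(s): ",
         paste(unique(setdiff(drugs$role, drug_roles())), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(drugs$drug_name) | is.na(drugs$drug_name))) {
    stop("empty drug_name in drugs table", call. = FALSE)
  }
  if (!all(outcomes$outcome %in% outcome_levels(all = TRUE))) {
    stop("invalid outcome value(s): ",
         paste(unique(setdiff(outcomes$outcome, outcome_levels(all = TRUE))),
               collapse = ", "), call. = FALSE)
  }
  no_drug <- setdiff(demo$report_id, drugs$report_id)
  if (length(no_drug)) {
    stop("report(s) without any drug entry: ",
         paste(utils::head(no_drug, 5), collapse = ", "), call. = FALSE)
  }
  has_reac <- reactions$report_id[!is.na(reactions$pt_code) |
                                    (!is.na(reactions$pt_term) &
                                       nzchar(reactions$pt_term))]
  no_reac <- setdiff(demo$report_id, has_reac)
  if (length(no_reac)) {
    stop("report(s) without any reaction: ",
         paste(utils::head(no_reac, 5), collapse = ", "), call. = FALSE)
  }

  rownames(demo) <- rownames(drugs) <- NULL
  rownames(reactions) <- rownames(outcomes) <- NULL
  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         outcomes = outcomes, provenance = provenance, log = log),
    class = "report_collection"
  )
}

drug_roles <- function() {
  c("primary_suspect", "secondary_suspect", "concomitant", "interacting")
}

#' Outcome categories
#'
#' The FAERS report-level outcome codes and their names in this package.
#' `all = TRUE` appends the residual `"other"` category (OT), which is stored
#' but excluded from rate comparisons.
#'
#' @param all include `"other"`?
#' @return character vector of outcome names.
#' @export
outcome_levels <- function(all = FALSE) {
  lv <- c("hospitalization", "disability", "life_threatening", "death",
          "required_intervention")
  if (all) c(lv, "other") else lv
}

outcome_code_map <- function() {
  c(HO = "hospitalization", DS = "disability", LT = "life_threatening",
    DE = "death", RI = "required_intervention", OT = "other")
}

role_code_map <- function() {
  c(PS = "primary_suspect", SS = "secondary_suspect", C = "concomitant",
    I = "interacting")
}

#' Number of reports in a collection
#' @param x a `report_collection`.
#' @return integer count.
#' @export
n_reports <- function(x) nrow(x$demo)

#' Report identifiers of a collection
#' @param x a `report_collection`.
#' @return character vector of `report_id`s, in storage order.
#' @export
report_ids <- function(x) x$demo$report_id

#' The load/generation log of a collection
#' @param x a `report_collection`.
#' @return character vector, one line per logged event.
#' @export
load_log <- function(x) x$log

#' @export
print.report_collection <- function(x, ...) {
  cat(sprintf("<report_collection> %d reports\n", n_reports(x)))
  cat(sprintf("  drug entries: %d | reaction rows: %d | outcome rows: %d\n",
              nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  cat(sprintf("  distinct cases: %d | distinct drugs: %d\n",
              length(unique(x$demo$case_id)),
              length(unique(x$drugs$drug_name))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (length(x$log)) cat(sprintf("  log: %d line(s)\n", length(x$log)))
  invisible(x)
}

# keep the given report ids (preserving demo order), subsetting all tables
subset_reports <- function(x, ids) {
  keep <- x$demo$report_id %in% ids
  report_collection(
    demo = x$demo[keep, , drop = FALSE],
    drugs = x$drugs[x$drugs$report_id %in% ids, , drop = FALSE],
    reactions = x$reactions[x$reactions$report_id %in% ids, , drop = FALSE],
    outcomes = x$outcomes[x$outcomes$report_id %in% ids, , drop = FALSE],
    provenance = x$provenance, log = x$log
  )
}

read_delim_table <- function(path, sep, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          comment.char = "", colClasses = "character",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s table (%s): required column(s) absent from header: %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read FAERS-style delimited report tables
#'
#' Loads the four-table quarterly layout into a validated
#' [report_collection]. Rows that cannot be parsed are dropped and logged,
#' never silently discarded; orphan drug/reaction/outcome rows (whose
#' `report_id` does not appear in the demographics table) raise a warning and
#' are skipped. Reports left without at least one drug entry and one reaction
#' are dropped (and logged), as the collection invariants require.
#'
#' Expected columns: demographics `report_id, case_id, age, sex, country,
#' year`; drugs `report_id, drug_name, role_code, dose, indication` (role
#' codes PS/SS/C/I); reactions `report_id` plus `pt_code` and/or `pt_term`;
#' outcomes `report_id, outcome_code` (letter codes HO, DS, LT, DE, RI, OT).
#'
#' @param demo_path,drug_path,reac_path,outc_path file paths.
#' @param dialect `"dollar_delimited"` (FAERS `$` separator) or
#'   `"comma_delimited"`.
#' @param synonyms optional drug-name synonym map, see
#'   [normalize_drug_name()].
#' @return a [report_collection]; the per-row drop log is available via
#'   [load_log()].
#' @export
read_reports <- function(demo_path, drug_path, reac_path, outc_path,
                         dialect = c("dollar_delimited", "comma_delimited"),
                         synonyms = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "dollar_delimited") "$" else ","
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  demo_raw <- read_delim_table(
    demo_path, sep, c("report_id", "case_id", "age", "sex", "country", "year"),
    "demographics")
  drug_raw <- read_delim_table(
    drug_path, sep, c("report_id", "drug_name", "role_code"), "drug")
  reac_raw <- read_delim_table(reac_path, sep, "report_id", "reaction")
  if (!any(c("pt_code", "pt_term") %in% names(reac_raw))) {
    stop("reaction table needs a pt_code and/or pt_term column", call. = FALSE)
  }
  outc_raw <- read_delim_table(
    outc_path, sep, c("report_id", "outcome_code"), "outcome")

  ## demographics
  ok <- !is.na(demo_raw$report_id) & !is.na(demo_raw$case_id)
  for (i in which(!ok)) {
    note("demo row %d dropped: missing report_id or case_id", i)
  }
  demo_raw <- demo_raw[ok, , drop = FALSE]
  dup <- duplicated(demo_raw$report_id)
  for (i in which(dup)) {
    note("demo row dropped: duplicate report_id %s (first kept)",
         demo_raw$report_id[i])
  }
  demo_raw <- demo_raw[!dup, , drop = FALSE]

  age <- suppressWarnings(as.numeric(demo_raw$age))
  bad <- !is.na(demo_raw$age) & (is.na(age) | age < 0 | age > 120)
  for (i in which(bad)) {
    note("report %s: unparseable or out-of-range age '%s' set to unknown",
         demo_raw$report_id[i], demo_raw$age[i])
  }
  age[bad] <- NA_real_

  sex <- tolower(trimws(ifelse(is.na(demo_raw$sex), "", demo_raw$sex)))
  sex <- ifelse(sex %in% c("m", "male"), "male",
                ifelse(sex %in% c("f", "female"), "female", "unknown"))

  year <- suppressWarnings(as.integer(demo_raw$year))
  for (i in which(!is.na(demo_raw$year) & is.na(year))) {
    note("report %s: unparseable year '%s' set to unknown",
         demo_raw$report_id[i], demo_raw$year[i])
  }

  demo <- data.frame(report_id = demo_raw$report_id,
                     case_id = demo_raw$case_id, age = age, sex = sex,
                     country = demo_raw$country, year = year,
                     stringsAsFactors = FALSE)
  known <- demo$report_id

  ## drugs
  orphan <- !drug_raw$report_id %in% known & !is.na(drug_raw$report_id)
  if (any(orphan)) {
    warning(sprintf("%d orphan drug row(s) skipped", sum(orphan)),
            call. = FALSE)
    for (i in which(orphan)) {
      note("drug row skipped: report_id %s not in demographics",
           drug_raw$report_id[i])
    }
  }
  drug_raw <- drug_raw[!orphan & !is.na(drug_raw$report_id), , drop = FALSE]
  role <- unname(role_code_map()[toupper(trimws(
    ifelse(is.na(drug_raw$role_code), "", drug_raw$role_code)))])
  name <- normalize_drug_name(ifelse(is.na(drug_raw$drug_name), "",
                                     drug_raw$drug_name), synonyms)
  bad <- is.na(role) | !nzchar(name)
  for (i in which(bad)) {
    note("drug row for report %s dropped: %s", drug_raw$report_id[i],
         if (!nzchar(name[i])) "empty drug name"
         else sprintf("unknown role code '%s'", drug_raw$role_code[i]))
  }
  drugs <- data.frame(
    report_id = drug_raw$report_id[!bad], drug_name = name[!bad],
    role = role[!bad],
    dose_text = (drug_raw$dose %||% rep(NA_character_, nrow(drug_raw)))[!bad],
    indication_pt = (drug_raw$indication %||%
                       rep(NA_character_, nrow(drug_raw)))[!bad],
    stringsAsFactors = FALSE)

  ## reactions
  orphan <- !reac_raw$report_id %in% known & !is.na(reac_raw$report_id)
  if (any(orphan)) {
    warning(sprintf("%d orphan reaction row(s) skipped", sum(orphan)),
            call. = FALSE)
    for (i in which(orphan)) {
      note("reaction row skipped: report_id %s not in demographics",
           reac_raw$report_id[i])
    }
  }
  reac_raw <- reac_raw[!orphan & !is.na(reac_raw$report_id), , drop = FALSE]
  code_chr <- reac_raw$pt_code %||% rep(NA_character_, nrow(reac_raw))
  term <- reac_raw$pt_term %||% rep(NA_character_, nrow(reac_raw))
  code <- suppressWarnings(as.integer(code_chr))
  bad_code <- !is.na(code_chr) & (is.na(code) | !grepl("^[0-9]{8}$",
                                                       trimws(code_chr)))
  for (i in which(bad_code)) {
    note("reaction row for report %s: malformed pt_code '%s' ignored",
         reac_raw$report_id[i], code_chr[i])
  }
  code[bad_code] <- NA_integer_
  empty <- is.na(code) & (is.na(term) | !nzchar(trimws(term)))
  for (i in which(empty)) {
    note("reaction row for report %s dropped: no usable pt_code or pt_term",
         reac_raw$report_id[i])
  }
  reactions <- data.frame(report_id = reac_raw$report_id[!empty],
                          pt_code = code[!empty], pt_term = term[!empty],
                          stringsAsFactors = FALSE)

  ## outcomes
  orphan <- !outc_raw$report_id %in% known & !is.na(outc_raw$report_id)
  if (any(orphan)) {
    warning(sprintf("%d orphan outcome row(s) skipped", sum(orphan)),
            call. = FALSE)
    for (i in which(orphan)) {
      note("outcome row skipped: report_id %s not in demographics",
           outc_raw$report_id[i])
    }
  }
  outc_raw <- outc_raw[!orphan & !is.na(outc_raw$report_id), , drop = FALSE]
  oc <- unname(outcome_code_map()[toupper(trimws(
    ifelse(is.na(outc_raw$outcome_code), "", outc_raw$outcome_code)))])
  for (i in which(is.na(oc))) {
    note("outcome row for report %s dropped: unknown code '%s'",
         outc_raw$report_id[i], outc_raw$outcome_code[i])
  }
  outcomes <- data.frame(report_id = outc_raw$report_id[!is.na(oc)],
                         outcome = oc[!is.na(oc)], stringsAsFactors = FALSE)
  outcomes <- unique(outcomes)

  ## a report must carry >= 1 drug and >= 1 reaction
  keep <- demo$report_id %in% drugs$report_id &
    demo$report_id %in% reactions$report_id
  for (i in which(!keep)) {
    note("report %s dropped: %s", demo$report_id[i],
         if (!demo$report_id[i] %in% drugs$report_id) "no drug entry"
         else "no reaction")
  }
  ids <- demo$report_id[keep]

  report_collection(
    demo = demo[keep, , drop = FALSE],
    drugs = drugs[drugs$report_id %in% ids, , drop = FALSE],
    reactions = reactions[reactions$report_id %in% ids, , drop = FALSE],
    outcomes = outcomes[outcomes$report_id %in% ids, , drop = FALSE],
    provenance = sprintf("read_reports(%s; dialect=%s)",
                         paste(basename(c(demo_path, drug_path, reac_path,
                                          outc_path)), collapse = ","),
                         dialect),
    log = log
  )
}

#' Write a report collection back to FAERS-style delimited tables
#'
#' Inverse of [read_reports()]: emits `demo`, `drug`, `reac` and `outc`
#' tables (with the reader's expected headers and letter codes) so a
#' collection round-trips through the file format.
#'
#' @param x a `report_collection`.
#' @param dir output directory (created if needed).
#' @param dialect delimiter dialect, as in [read_reports()].
#' @return invisibly, a named character vector of the four file paths.
#' @export
write_reports <- function(x, dir,
                          dialect = c("dollar_delimited", "comma_delimited")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "dollar_delimited") "$" else ","
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  inv_role <- setNames(names(role_code_map()), role_code_map())
  inv_outc <- setNames(names(outcome_code_map()), outcome_code_map())

  demo <- x$demo
  drug <- data.frame(report_id = x$drugs$report_id,
                     drug_name = x$drugs$drug_name,
                     role_code = unname(inv_role[x$drugs$role]),
                     dose = x$drugs$dose_text,
                     indication = x$drugs$indication_pt,
                     stringsAsFactors = FALSE)
  reac <- data.frame(report_id = x$reactions$report_id,
                     pt_code = ifelse(is.na(x$reactions$pt_code), NA,
                                      sprintf("%08d", x$reactions$pt_code)),
                     pt_term = x$reactions$pt_term, stringsAsFactors = FALSE)
  outc <- data.frame(report_id = x$outcomes$report_id,
                     outcome_code = unname(inv_outc[x$outcomes$outcome]),
                     stringsAsFactors = FALSE)

  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"),
             outc = file.path(dir, "outc.txt"))
  wr <- function(df, path) {
    utils::write.table(df, path, sep = sep, quote = TRUE, na = "",
                       row.names = FALSE)
  }
  wr(demo, paths["demo"]); wr(drug, paths["drug"])
  wr(reac, paths["reac"]); wr(outc, paths["outc"])
  invisible(paths)
}

#' Deduplicate a collection by case identifier
#'
#' Spontaneous reporting systems carry several versions of the same case. For
#' each `case_id` exactly one report is retained: the one with the
#' lexicographically greatest `report_id`, a deterministic proxy for the most
#' recent version (later FAERS versions supersede earlier ones). Idempotent;
#' never changes the set of distinct `case_id`s.
#'
#' @param x a `report_collection`.
#' @return a `report_collection` with one report per case.
#' @export
deduplicate <- function(x) {
  d <- x$demo[order(x$demo$case_id, x$demo$report_id), , drop = FALSE]
  keep_ids <- d$report_id[!duplicated(d$case_id, fromLast = TRUE)]
  subset_reports(x, keep_ids)
}

#' Restrict a collection to primary-suspect reports for one drug
#'
#' Keeps the reports that contain at least one drug entry whose normalized
#' name equals `drug_name` with role `primary_suspect`. Report-level
#' membership: a report with several matching entries is included once.
#'
#' @param x a `report_collection`.
#' @param drug_name drug name (normalized internally).
#' @param synonyms optional synonym map, see [normalize_drug_name()].
#' @return a `report_collection` (possibly empty-free: reports only).
#' @export
filter_primary_suspect <- function(x, drug_name, synonyms = NULL) {
  nm <- normalize_drug_name(drug_name, synonyms)
  hit <- x$drugs$drug_name == nm & x$drugs$role == "primary_suspect"
  ids <- unique(x$drugs$report_id[hit])
  subset_reports(x, ids)
}

# report ids with the drug as primary suspect (no subsetting)
primary_suspect_ids <- function(x, drug_name) {
  nm <- normalize_drug_name(drug_name)
  unique(x$drugs$report_id[x$drugs$drug_name == nm &
                             x$drugs$role == "primary_suspect"])
}
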