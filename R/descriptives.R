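age_strata_levels <- function() {
  c("<=44", "45-59", "60-74", ">=75", "unknown")
}

year_period_levels <- function() {
  c("2003-2007", "2008-2012", "2013-2017", "2018-2023", "other")
}

#' Stratified clinical characteristics of a report cohort
#'
#' Summarizes a drug-specific cohort (typically the deduplicated,
#' SMQ-positive, primary-suspect reports for one drug) the way
#' pharmacovigilance case series are tabulated: age strata (<=44 meaning
#' age < 45, 45-59, 60-74, >=75, unknown), mean +/- sample SD over known
#' ages, sex, reporting country, and four 5-year reporting periods spanning
#' 2003-2023 (years outside fall into "other" rather than erroring).
#'
#' Every percentage uses the full cohort size (unknowns included) as
#' denominator, computed as `100 * count / n_total` and rounded half-up to
#' 2 decimals, so within each block the counts sum to `n_total` and the
#' unrounded percentages to 100.
#'
#' @param x a `report_collection` holding the cohort.
#' @param drug_name optional label carried into the summary.
#' @return an object of class `cohort_summary`: `n_total`, `age_strata`,
#'   `age_mean`, `age_sd`, `sex_counts`, `country_counts`,
#'   `year_period_counts` (each block a data frame of `level`, `n`, `pct`).
#' @export
summarize_cohort <- function(x, drug_name = NA_character_) {
  n_total <- n_reports(x)
  block <- function(levels, values) {
    cnt <- table(factor(values, levels = levels))
    data.frame(level = levels, n = as.integer(cnt),
               pct = pct2(as.integer(cnt), n_total),
               stringsAsFactors = FALSE)
  }

  age <- x$demo$age
  stratum <- ifelse(is.na(age), "unknown",
                    ifelse(age < 45, "<=44",
                           ifelse(age < 60, "45-59",
                                  ifelse(age < 75, "60-74", ">=75"))))
  known <- age[!is.na(age)]

  yr <- x$demo$year
  period <- ifelse(is.na(yr), "other",
                   ifelse(yr >= 2003 & yr <= 2007, "2003-2007",
                          ifelse(yr >= 2008 & yr <= 2012, "2008-2012",
                                 ifelse(yr >= 2013 & yr <= 2017, "2013-2017",
                                        ifelse(yr >= 2018 & yr <= 2023,
                                               "2018-2023", "other")))))

  country <- ifelse(is.na(x$demo$country), "unknown", x$demo$country)
  ctab <- table(country)
  country_counts <- data.frame(level = as.character(names(ctab) %||%
                                                      character(0)),
                               n = as.integer(ctab),
                               pct = pct2(as.integer(ctab), n_total),
                               stringsAsFactors = FALSE)
  country_counts <- country_counts[order(-country_counts$n,
                                         country_counts$level), , drop = FALSE]
  rownames(country_counts) <- NULL

  structure(
    list(drug = drug_name, n_total = n_total,
         age_strata = block(age_strata_levels(), stratum),
         age_mean = if (length(known)) mean(known) else NA_real_,
         age_sd = if (length(known) > 1) stats::sd(known) else NA_real_,
         n_age_known = length(known),
         sex_counts = block(c("male", "female", "unknown"), x$demo$sex),
         country_counts = country_counts,
         year_period_counts = block(year_period_levels(), period)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary>%s N = %d\n",
              if (!is.na(x$drug)) paste0(" drug=", x$drug) else "",
              x$n_total))
  pb <- function(title, df, top = NULL) {
    cat(title, "\n")
    if (!is.null(top)) df <- utils::head(df, top)
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-12s %5d (%s%%)\n", df$level[i], df$n[i],
                  formatC(df$pct[i], format = "f", digits = 2)))
    }
  }
  pb("Age", x$age_strata)
  if (!is.na(x$age_mean)) {
    cat(sprintf("  mean +/- SD  %.2f +/- %s  (over %d known)\n",
                x$age_mean,
                if (is.na(x$age_sd)) "n.e." else sprintf("%.2f", x$age_sd),
                x$n_age_known))
  }
  pb("Sex", x$sex_counts)
  pb("Country (top 5)", x$country_counts, top = 5)
  pb("Reporting period", x$year_period_counts)
  invisible(x)
}

#' Top-k dose, indication and co-medication tallies for a drug cohort
#'
#' Mirrors the context columns of a case-series table: the most frequent
#' dose strings and indication PTs attached to the analyzed drug's
#' primary-suspect entries, and the most frequent co-reported drugs (entries
#' with any non-primary-suspect role, so the analyzed drug's own
#' primary-suspect entries are excluded by construction). Counts are
#' report-level; ties are broken alphabetically; `k` larger than the number
#' of distinct values returns the full list.
#'
#' @param x a `report_collection` holding the cohort.
#' @param drug_name the analyzed drug.
#' @param k list length; default 10.
#' @return list of three data frames (`dose`, `indication`, `co_drugs`),
#'   each with columns `value`, `n`.
#' @export
summarize_drug_context <- function(x, drug_name, k = 10) {
  nm <- normalize_drug_name(drug_name)
  topk <- function(report_id, value) {
    keep <- !is.na(value) & nzchar(trimws(value))
    key <- unique(data.frame(report_id = report_id[keep],
                             value = trimws(value[keep]),
                             stringsAsFactors = FALSE))
    tab <- table(key$value)
    out <- data.frame(value = as.character(names(tab) %||% character(0)),
                      n = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(-out$n, out$value), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, k)
  }
  own <- x$drugs$drug_name == nm & x$drugs$role == "primary_suspect"
  co <- x$drugs$role != "primary_suspect"
  list(
    dose = topk(x$drugs$report_id[own], x$drugs$dose_text[own]),
    indication = topk(x$drugs$report_id[own], x$drugs$indication_pt[own]),
    co_drugs = topk(x$drugs$report_id[co], x$drugs$drug_name[co])
  )
}
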