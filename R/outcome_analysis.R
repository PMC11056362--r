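#' Per-drug outcome rates
#'
#' For each drug cohort (typically the deduplicated, SMQ-positive,
#' primary-suspect reports) and each severity outcome, the rate is the
#' number of reports carrying that outcome code divided by the cohort size.
#' A report with several outcomes counts once in each category. Drugs with
#' an empty cohort get `NA` rates and are excluded from comparisons.
#'
#' @param cohorts named list of `report_collection`s, one per drug.
#' @param outcomes outcome categories to tabulate; default the five
#'   severity outcomes (see [outcome_levels()]).
#' @return data frame with columns `drug`, `outcome`, `n_with_outcome`,
#'   `n_total`, `rate`.
#' @export
outcome_rates <- function(cohorts, outcomes = outcome_levels()) {
  rows <- lapply(names(cohorts), function(d) {
    x <- cohorts[[d]]
    n_tot <- n_reports(x)
    n_with <- vapply(outcomes, function(oc) {
      length(unique(x$outcomes$report_id[x$outcomes$outcome == oc]))
    }, integer(1))
    data.frame(drug = d, outcome = outcomes, n_with_outcome = n_with,
               n_total = n_tot,
               rate = if (n_tot > 0) n_with / n_tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 2x2 (or k x 2) association test: Fisher's exact when any expected cell
# is < 5, else Pearson chi-square without continuity correction.
assoc_test <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(E < 5)) {
    list(p = stats::fisher.test(m)$p.value, test = "fisher_exact")
  } else {
    list(p = unname(stats::chisq.test(m, correct = FALSE)$p.value),
         test = "pearson_chi2")
  }
}

#' Compare one outcome's rate across drugs
#'
#' Builds the drugs x \{outcome, no outcome\} table over the non-empty
#' cohorts and tests it two ways: an omnibus test across all drugs, and all
#' pairwise 2x2 tests with Bonferroni correction (adjusted p = min(1,
#' raw p x number of pairwise tests for this outcome)). Each table uses
#' Fisher's exact test (two-sided, sum of all hypergeometric outcomes no
#' more probable than the observed table) when any expected cell is below
#' 5, else Pearson's chi-square without continuity correction.
#'
#' @param outcome one of [outcome_levels()].
#' @param cohorts named list of `report_collection`s, one per drug; at
#'   least two must be non-empty.
#' @param alpha significance threshold applied to the adjusted p-values.
#' @return an object of class `outcome_comparison`: `outcome`, `per_drug`
#'   (counts and rates), `omnibus_p`, `omnibus_test`, `pairwise` (data
#'   frame of `drug_i`, `drug_j`, `raw_p`, `adjusted_p`, `test_used`,
#'   `significant`), `n_comparisons`, `alpha`.
#' @export
compare_outcome <- function(outcome, cohorts, alpha = 0.05) {
  stopifnot(outcome %in% outcome_levels(all = TRUE))
  rates <- outcome_rates(cohorts, outcomes = outcome)
  rates <- rates[rates$n_total > 0, , drop = FALSE]
  if (nrow(rates) < 2) {
    stop("compare_outcome needs at least two drugs with non-empty cohorts",
         call. = FALSE)
  }
  m_all <- cbind(with_outcome = rates$n_with_outcome,
                 without = rates$n_total - rates$n_with_outcome)
  rownames(m_all) <- rates$drug
  omni <- assoc_test(m_all)

  pairs <- utils::combn(rates$drug, 2)
  n_cmp <- ncol(pairs)
  pw <- lapply(seq_len(n_cmp), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- assoc_test(m_all[c(i, j), , drop = FALSE])
    data.frame(drug_i = i, drug_j = j, raw_p = res$p,
               adjusted_p = min(1, res$p * n_cmp), test_used = res$test,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$significant <- pw$adjusted_p < alpha
  rownames(pw) <- NULL

  structure(list(outcome = outcome, per_drug = rates,
                 omnibus_p = omni$p, omnibus_test = omni$test,
                 pairwise = pw, n_comparisons = n_cmp, alpha = alpha),
            class = "outcome_comparison")
}

#' @export
print.outcome_comparison <- function(x, ...) {
  cat(sprintf("<outcome_comparison> %s\n", x$outcome))
  for (i in seq_len(nrow(x$per_drug))) {
    cat(sprintf("  %-14s %4d / %4d  (%.2f%%)\n", x$per_drug$drug[i],
                x$per_drug$n_with_outcome[i], x$per_drug$n_total[i],
                100 * x$per_drug$rate[i]))
  }
  cat(sprintf("  omnibus: p = %.4g (%s)\n", x$omnibus_p, x$omnibus_test))
  cat(sprintf("  pairwise (Bonferroni x%d, alpha = %g):\n",
              x$n_comparisons, x$alpha))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("    %s vs %s: p = %.4g, adj = %.4g (%s)%s\n",
                x$pairwise$drug_i[i], x$pairwise$drug_j[i],
                x$pairwise$raw_p[i], x$pairwise$adjusted_p[i],
                x$pairwise$test_used[i],
                if (x$pairwise$significant[i]) "  *" else ""))
  }
  invisible(x)
}

#' Compare all severity outcomes across drugs
#'
#' Runs [compare_outcome()] for each of the five severity outcome
#' categories; Bonferroni correction is applied per outcome across its
#' pairwise tests, not across outcomes.
#'
#' @param cohorts named list of `report_collection`s.
#' @param alpha significance threshold.
#' @return named list of `outcome_comparison` objects.
#' @export
compare_outcomes <- function(cohorts, alpha = 0.05) {
  setNames(lapply(outcome_levels(), compare_outcome, cohorts = cohorts,
                  alpha = alpha),
           outcome_levels())
}
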