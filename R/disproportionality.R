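#' A drug-event 2x2 contingency table
#'
#' Report-level counts over a deduplicated collection, partitioned by the
#' suspect drug and the suspect event:
#' \preformatted{
#'                 event     other events
#'   suspect drug    a            c
#'   other drugs     b            d
#' }
#' `a` counts reports containing both the suspect drug (as primary suspect)
#' and the suspect event; `b` the event with other medications; `c` the drug
#' with other events; `d` neither. The comparator universe for `b` and `d`
#' is the entire collection (all other drugs).
#'
#' @param a,b,c,d non-negative integer cell counts; their sum must be > 0.
#' @param drug,event optional labels carried along for printing.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              event = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("all cells must be non-negative counts", call. = FALSE)
  }
  if (sum(cells) <= 0) stop("empty table: a+b+c+d must be > 0", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n_total = as.numeric(a + b + c + d),
                 drug = drug, event = event),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table>%s%s\n",
              if (!is.na(x$drug)) paste0(" drug=", x$drug) else "",
              if (!is.na(x$event)) paste0(" event=", x$event) else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2,
              dimnames = list(c("suspect drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one drug-event pair
#'
#' The event is defined by an `smq_definition` (report-level membership of
#' any member PT), a single PT (integer code or term string), or an explicit
#' character vector of event-positive `report_id`s. Drug exposure means the
#' drug appears with role `primary_suspect`. The four cells partition the
#' collection, so they always sum to `n_reports(x)`.
#'
#' @param x a deduplicated `report_collection` (the full comparator
#'   universe, all drugs).
#' @param drug_name suspect drug (normalized internally).
#' @param event an `smq_definition`, a PT code (numeric), a PT term
#'   (character scalar), or a character vector of event-positive report ids.
#' @return a [contingency_table].
#' @export
build_contingency <- function(x, drug_name, event) {
  if (n_reports(x) == 0) {
    stop("empty collection: contingency table needs N_total > 0",
         call. = FALSE)
  }
  ev_label <- NA_character_
  if (inherits(event, "smq_definition")) {
    ev_ids <- smq_report_ids(x, event)
    ev_label <- paste0("SMQ:", event$name)
  } else if (is.numeric(event) && length(event) == 1) {
    r <- x$reactions
    ev_ids <- unique(r$report_id[!is.na(r$pt_code) & r$pt_code == event])
    ev_label <- paste0("PT:", format(event, scientific = FALSE))
  } else if (is.character(event) && length(event) == 1 &&
             !event %in% report_ids(x)) {
    r <- x$reactions
    ev_ids <- unique(r$report_id[tolower(r$pt_term) == tolower(event)])
    ev_label <- paste0("PT:", event)
  } else if (is.character(event)) {
    ev_ids <- unique(event)
  } else {
    stop("unsupported event specification", call. = FALSE)
  }
  ids <- report_ids(x)
  ps <- ids %in% primary_suspect_ids(x, drug_name)
  ev <- ids %in% ev_ids
  contingency_table(a = sum(ps & ev), b = sum(!ps & ev),
                    c = sum(ps & !ev), d = sum(!ps & !ev),
                    drug = normalize_drug_name(drug_name), event = ev_label)
}

# Haldane-Anscombe: +0.5 on all four cells when any raw cell is zero.
# Applied to the ratio estimators (ROR, PRR, IC) only; chi-squared stays on
# the raw counts.
corrected_cells <- function(tab) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
       n = sum(cells), corrected = corrected)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (a/b)/(c/d); the two-sided 95% CI is symmetric on the log scale,
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero, the Haldane correction (add 0.5 to all four cells) is applied
#' first and flagged, keeping the estimator finite.
#'
#' @param tab a [contingency_table].
#' @return list with `ror`, `ci_low`, `ci_high`, `zero_corrected`.
#' @export
compute_ror <- function(tab) {
  cc <- corrected_cells(tab)
  ror <- (cc$a / cc$b) / (cc$c / cc$d)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  list(ror = ror, ci_low = ror * exp(-1.96 * se),
       ci_high = ror * exp(1.96 * se), zero_corrected = cc$corrected)
}

#' Proportional reporting ratio and Pearson chi-squared statistic
#'
#' PRR = (a/(a+c)) / (b/(b+d)): the event's share among the suspect drug's
#' reports over its share among all other reports. The accompanying
#' chi-squared statistic is Pearson's sum over all four cells,
#' `sum((O-E)^2/E)` with `E = row margin x column margin / N`, computed on
#' the raw (uncorrected) counts with no continuity correction by default.
#' `chi2_mode = "a_cell_only"` restricts the sum to the a-cell, a literal
#' reading of some published formulations. A raw margin of zero makes the
#' statistic degenerate; it is reported as 0 with `degenerate = TRUE`.
#'
#' @param tab a [contingency_table].
#' @param chi2_mode `"all_cells"` (default, standard Pearson) or
#'   `"a_cell_only"`.
#' @param yates apply the Yates continuity correction? Default `FALSE`.
#' @return list with `prr`, `chi2`, `zero_corrected`, `degenerate`.
#' @export
compute_prr <- function(tab, chi2_mode = c("all_cells", "a_cell_only"),
                        yates = FALSE) {
  chi2_mode <- match.arg(chi2_mode)
  cc <- corrected_cells(tab)
  prr <- (cc$a / (cc$a + cc$c)) / (cc$b / (cc$b + cc$d))

  O <- c(tab$a, tab$b, tab$c, tab$d)
  n <- tab$n_total
  row_m <- c(tab$a + tab$c, tab$b + tab$d)  # drug margins
  col_m <- c(tab$a + tab$b, tab$c + tab$d)  # event margins
  degenerate <- any(row_m == 0) || any(col_m == 0)
  if (degenerate) {
    chi2 <- 0
  } else {
    E <- c(row_m[1] * col_m[1], row_m[2] * col_m[1],
           row_m[1] * col_m[2], row_m[2] * col_m[2]) / n
    dev <- abs(O - E)
    if (yates) dev <- pmax(dev - 0.5, 0)
    terms <- dev^2 / E
    chi2 <- if (chi2_mode == "all_cells") sum(terms) else terms[1]
  }
  list(prr = prr, chi2 = chi2, zero_corrected = cc$corrected,
       degenerate = degenerate)
}

#' BCPNN information component and its lower 95% limit
#'
#' IC = log2( a * N / ((a+c) * (a+b)) ), the log2 observed-to-expected
#' co-reporting ratio. The lower limit is evaluated multiplicatively as
#' `IC025 = exp(ln(IC) - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`; this form
#' (rather than the classical posterior credible interval) is
#' self-consistent with the published signal tables this package mirrors.
#' It requires IC > 0; for IC <= 0 the limit is not evaluable and is
#' returned as `NA` (and the BCPNN criterion cannot fire). The alternative
#' additive mode `ic_mode = "ic_minus_2sd"` returns
#' `IC - 1.96 * sd` on the log2 scale instead.
#'
#' @param tab a [contingency_table].
#' @param ic_mode `"multiplicative"` (default) or `"ic_minus_2sd"`.
#' @return list with `ic`, `ic025`, `zero_corrected`.
#' @export
compute_ic <- function(tab, ic_mode = c("multiplicative", "ic_minus_2sd")) {
  ic_mode <- match.arg(ic_mode)
  cc <- corrected_cells(tab)
  ic <- log2(cc$a * cc$n / ((cc$a + cc$c) * (cc$a + cc$b)))
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  ic025 <- if (ic_mode == "ic_minus_2sd") {
    ic - 1.96 * se
  } else if (ic > 0) {
    exp(log(ic) - 1.96 * se)
  } else {
    NA_real_
  }
  list(ic = ic, ic025 = ic025, zero_corrected = cc$corrected)
}

#' Evaluate the three disproportionality algorithms on one table
#'
#' Computes ROR (with 95% CI), PRR (with Pearson chi-squared) and the BCPNN
#' information component, then applies the standard positivity criteria:
#' \itemize{
#'   \item ROR: CI lower bound > 1 and N >= 2;
#'   \item PRR: PRR >= 2, chi-squared >= 4 and N >= 3;
#'   \item BCPNN: IC025 > 0;
#' }
#' where N is the co-occurrence count `a`. The pair is a positive signal
#' when any one algorithm meets its criteria.
#'
#' @param tab a [contingency_table].
#' @param chi2_mode,yates passed to [compute_prr()].
#' @param ic_mode passed to [compute_ic()].
#' @return an object of class `signal_result`: a list with `n`, `ror`,
#'   `ror_ci`, `prr`, `chi2`, `ic`, `ic025`, `zero_corrected`,
#'   `degenerate`, the per-algorithm flags `ror_positive`, `prr_positive`,
#'   `bcpnn_positive`, and the overall `positive`.
#' @export
evaluate_signal <- function(tab, chi2_mode = "all_cells", yates = FALSE,
                            ic_mode = "multiplicative") {
  ror <- compute_ror(tab)
  prr <- compute_prr(tab, chi2_mode = chi2_mode, yates = yates)
  ic <- compute_ic(tab, ic_mode = ic_mode)
  n <- tab$a
  ror_pos <- ror$ci_low > 1 && n >= 2
  prr_pos <- prr$prr >= 2 && prr$chi2 >= 4 && n >= 3
  bcpnn_pos <- !is.na(ic$ic025) && ic$ic025 > 0
  structure(
    list(drug = tab$drug, event = tab$event, n = n,
         ror = ror$ror, ror_ci = c(low = ror$ci_low, high = ror$ci_high),
         prr = prr$prr, chi2 = prr$chi2, ic = ic$ic, ic025 = ic$ic025,
         zero_corrected = ror$zero_corrected, degenerate = prr$degenerate,
         ror_positive = ror_pos, prr_positive = prr_pos,
         bcpnn_positive = bcpnn_pos,
         positive = ror_pos || prr_pos || bcpnn_pos),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  f <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  cat(sprintf("<signal_result>%s%s\n",
              if (!is.na(x$drug)) paste0(" drug=", x$drug) else "",
              if (!is.na(x$event)) paste0(" event=", x$event) else ""))
  cat(sprintf("  N = %d%s\n", as.integer(x$n),
              if (x$zero_corrected) "  [zero cell: Haldane +0.5]" else ""))
  cat(sprintf("  PRR (chi2)      : %s (%s)%s\n", f(x$prr), f(x$chi2),
              if (x$degenerate) " [degenerate margins]" else ""))
  cat(sprintf("  ROR (95%% CI)    : %s (%s-%s)\n", f(x$ror),
              f(x$ror_ci["low"]), f(x$ror_ci["high"])))
  cat(sprintf("  IC (IC025)      : %s (%s)\n", f(x$ic),
              if (is.na(x$ic025)) "n.e." else f(x$ic025)))
  crit <- c(ROR = x$ror_positive, PRR = x$prr_positive,
            BCPNN = x$bcpnn_positive)
  cat(sprintf("  criteria met    : %s\n",
              if (any(crit)) paste(names(crit)[crit], collapse = ", ")
              else "none"))
  cat(sprintf("  signal          : %s\n",
              if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' @export
as.data.frame.signal_result <- function(x, ...) {
  data.frame(drug = x$drug, event = x$event, n = as.integer(x$n),
             prr = x$prr, chi2 = x$chi2, ror = x$ror,
             ror_low = unname(x$ror_ci["low"]),
             ror_high = unname(x$ror_ci["high"]),
             ic = x$ic, ic025 = x$ic025,
             zero_corrected = x$zero_corrected, degenerate = x$degenerate,
             ror_positive = x$ror_positive, prr_positive = x$prr_positive,
             bcpnn_positive = x$bcpnn_positive, positive = x$positive,
             stringsAsFactors = FALSE)
}

#' Signal table for several drugs against one event definition
#'
#' Convenience wrapper: one [evaluate_signal()] row per drug against the
#' same event (typically an SMQ), in the layout of published signal-strength
#' tables (drug, N, PRR (chi2), ROR (95% CI), IC (IC025), flags).
#'
#' @param x a deduplicated `report_collection`.
#' @param drug_names character vector of drugs to test.
#' @param event event definition, as in [build_contingency()].
#' @param ... passed to [evaluate_signal()].
#' @return data frame, one row per drug (full precision).
#' @export
signal_table <- function(x, drug_names, event, ...) {
  rows <- lapply(drug_names, function(d) {
    as.data.frame(evaluate_signal(build_contingency(x, d, event), ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a signal table for display
#'
#' Rounds to 2 decimals (half-up) and collapses the columns into the
#' conventional `PRR (chi2)` / `ROR (95% CI)` / `IC (IC025)` strings.
#' Sparse rows (N below `min_n`) can be masked with dashes.
#'
#' @param tab data frame from [signal_table()] or
#'   `as.data.frame(<signal_result>)`.
#' @param min_n if not `NULL`, rows with `n < min_n` are shown as dashes.
#' @return data frame of display strings.
#' @export
format_signal_table <- function(tab, min_n = NULL) {
  f <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  out <- data.frame(
    drug = tab$drug, event = tab$event, N = as.integer(tab$n),
    `PRR (chi2)` = sprintf("%s (%s)", f(tab$prr), f(tab$chi2)),
    `ROR (95% CI)` = sprintf("%s (%s-%s)", f(tab$ror), f(tab$ror_low),
                             f(tab$ror_high)),
    `IC (IC025)` = sprintf("%s (%s)", f(tab$ic),
                           ifelse(is.na(tab$ic025), "n.e.", f(tab$ic025))),
    signal = ifelse(tab$positive, "yes", "no"),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(min_n)) {
    mask <- out$N < min_n
    out[mask, c("PRR (chi2)", "ROR (95% CI)", "IC (IC025)", "signal")] <- "-"
  }
  out
}
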