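#' Configuration of a full signal-detection study
#'
#' Collects everything [run_study()] needs: either the four input table
#' paths (real data) or a [synth_config()] (simulated data), the SMQ
#' defining the event of interest (defaulting to the packaged narrow
#' hearing-impairment query), the drugs to analyze, and the analysis
#' options.
#'
#' @param drugs non-empty character vector of drugs to analyze.
#' @param demo_path,drug_path,reac_path,outc_path input table paths
#'   (ignored when `synth` is given).
#' @param synth optional `synth_config`; when present the study runs on
#'   generated data.
#' @param smq an `smq_definition` or path to an SMQ file; default the
#'   packaged hearing-impairment narrow SMQ.
#' @param dialect input delimiter dialect, see [read_reports()].
#' @param synonyms drug-name synonym map, see [normalize_drug_name()].
#' @param chi2_mode,yates,ic_mode see [evaluate_signal()].
#' @param pt_min_n minimum per-PT report count in breakdowns (default 3).
#' @param apply_pt_filter apply the minimum-count PT filter?
#' @param alpha significance threshold for outcome comparisons, in (0, 1).
#' @return an object of class `study_config`.
#' @export
study_config <- function(drugs,
                         demo_path = NULL, drug_path = NULL,
                         reac_path = NULL, outc_path = NULL,
                         synth = NULL, smq = NULL,
                         dialect = "dollar_delimited", synonyms = NULL,
                         chi2_mode = "all_cells", yates = FALSE,
                         ic_mode = "multiplicative",
                         pt_min_n = 3, apply_pt_filter = TRUE,
                         alpha = 0.05) {
  if (length(drugs) == 0) stop("drug list must be non-empty", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  if (is.null(synth) &&
      (is.null(demo_path) || is.null(drug_path) || is.null(reac_path) ||
         is.null(outc_path))) {
    stop("provide either the four table paths or a synth config",
         call. = FALSE)
  }
  structure(list(drugs = normalize_drug_name(drugs, synonyms),
                 demo_path = demo_path, drug_path = drug_path,
                 reac_path = reac_path, outc_path = outc_path,
                 synth = synth, smq = smq, dialect = dialect,
                 synonyms = synonyms, chi2_mode = chi2_mode, yates = yates,
                 ic_mode = ic_mode, pt_min_n = pt_min_n,
                 apply_pt_filter = apply_pt_filter, alpha = alpha),
            class = "study_config")
}

#' Run the full signal-detection study
#'
#' Executes the pipeline stage by stage: load (or generate) -> deduplicate
#' -> per-drug primary-suspect filter -> SMQ classification -> SMQ-level
#' contingency and signal evaluation -> per-PT signal breakdown ->
#' descriptives -> outcome comparisons. Any stage error is rethrown with
#' the stage name. Drugs absent from the data get present-but-degenerate
#' sections and a warning; the run manifest records row counts after every
#' stage (non-increasing through dedup and filtering).
#'
#' @param config a [study_config()].
#' @param seed seed for data generation when `config$synth` is set.
#' @return an object of class `faers_study`: `signals` (SMQ-level data
#'   frame), `signal_results` (list of `signal_result`), `pt_signals`
#'   (per-drug data frames), `pt_counts`, `cohort_summaries`, `contexts`,
#'   `outcome_rates`, `outcome_comparisons`, `manifest`, `log`.
#' @export
run_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("study failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  coll <- stage("load", {
    if (!is.null(config$synth)) {
      generate_reports(config$synth, seed = seed)
    } else {
      read_reports(config$demo_path, config$drug_path, config$reac_path,
                   config$outc_path, dialect = config$dialect,
                   synonyms = config$synonyms)
    }
  })
  n_loaded <- n_reports(coll)

  dd <- stage("deduplicate", deduplicate(coll))
  n_dedup <- n_reports(dd)

  smq <- stage("smq", {
    if (is.null(config$smq)) hearing_impairment_smq()
    else if (inherits(config$smq, "smq_definition")) config$smq
    else load_smq(config$smq)
  })

  signal_results <- list(); pt_signals <- list(); pt_counts <- list()
  cohort_summaries <- list(); contexts <- list(); cohorts <- list()
  counts <- list()
  for (d in config$drugs) {
    ps <- stage("primary_suspect_filter", filter_primary_suspect(dd, d))
    if (n_reports(ps) == 0) {
      warning(sprintf("drug '%s' has no primary-suspect reports", d),
              call. = FALSE)
    }
    cohort <- stage("smq_classification",
                    subset_reports(ps, intersect(report_ids(ps),
                                                 smq_report_ids(ps, smq))))
    counts[[d]] <- c(primary_suspect = n_reports(ps),
                     smq_positive = n_reports(cohort))

    signal_results[[d]] <- stage("signal", {
      evaluate_signal(build_contingency(dd, d, smq),
                      chi2_mode = config$chi2_mode, yates = config$yates,
                      ic_mode = config$ic_mode)
    })
    pt_counts[[d]] <- stage("pt_breakdown",
                            pt_breakdown(dd, d, smq, min_n = config$pt_min_n,
                                         apply_min_n = config$apply_pt_filter))
    pt_signals[[d]] <- stage("pt_signal", {
      pts <- pt_counts[[d]]
      if (nrow(pts) == 0) {
        cbind(data.frame(term = character()),
              signal_table(dd, character(0), smq))
      } else {
        rows <- lapply(seq_len(nrow(pts)), function(i) {
          res <- evaluate_signal(build_contingency(dd, d, pts$code[i]),
                                 chi2_mode = config$chi2_mode,
                                 yates = config$yates,
                                 ic_mode = config$ic_mode)
          cbind(data.frame(term = pts$term[i], stringsAsFactors = FALSE),
                as.data.frame(res))
        })
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
      }
    })
    cohort_summaries[[d]] <- stage("descriptives",
                                   summarize_cohort(cohort, d))
    contexts[[d]] <- stage("descriptives",
                           summarize_drug_context(cohort, d))
    cohorts[[d]] <- cohort
  }

  rates <- stage("outcomes", outcome_rates(cohorts))
  comparisons <- stage("outcomes", {
    nonempty <- sum(vapply(cohorts, n_reports, integer(1)) > 0)
    if (nonempty >= 2) compare_outcomes(cohorts, alpha = config$alpha)
    else NULL
  })

  signals <- do.call(rbind, lapply(signal_results, as.data.frame))
  rownames(signals) <- NULL

  manifest <- list(
    package = "pvsignal",
    seed = seed %||% (if (!is.null(config$synth)) config$synth$seed else NA),
    options = list(chi2_mode = config$chi2_mode, yates = config$yates,
                   ic_mode = config$ic_mode, pt_min_n = config$pt_min_n,
                   apply_pt_filter = config$apply_pt_filter,
                   alpha = config$alpha, dialect = config$dialect),
    drugs = config$drugs, smq = smq$name, smq_n_members = nrow(smq$members),
    stage_counts = list(loaded = n_loaded, deduplicated = n_dedup,
                        per_drug = counts)
  )

  structure(list(signals = signals, signal_results = signal_results,
                 pt_signals = pt_signals, pt_counts = pt_counts,
                 cohort_summaries = cohort_summaries, contexts = contexts,
                 outcome_rates = rates, outcome_comparisons = comparisons,
                 manifest = manifest, log = load_log(coll)),
            class = "faers_study")
}

#' @export
print.faers_study <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("<faers_study>\n")
  cat(sprintf("  reports: %d loaded -> %d after deduplication\n",
              sc$loaded, sc$deduplicated))
  cat(sprintf("  event set: %s (%d PTs)\n", x$manifest$smq,
              x$manifest$smq_n_members))
  cat("  SMQ-level signals:\n")
  disp <- format_signal_table(x$signals)
  for (i in seq_len(nrow(disp))) {
    cat(sprintf("    %-14s N=%-5d PRR(chi2)=%-18s ROR(CI)=%-22s %s\n",
                disp$drug[i], disp$N[i], disp$`PRR (chi2)`[i],
                disp$`ROR (95% CI)`[i],
                ifelse(disp$signal[i] == "yes", "POSITIVE", "")))
  }
  invisible(x)
}

#' Write study outputs to delimited tables
#'
#' Emits the result tables named after their conventional layouts --
#' `table3_characteristics.tsv` (stratified cohort descriptives),
#' `table4_context.tsv` (dose/indication/co-medication tallies),
#' `table5_smq_signals.tsv` (+ `_display`), `table6_pt_signals.tsv`
#' (+ `_display`), `fig2_outcomes.tsv` (rates) and
#' `fig2_outcome_tests.tsv` (pairwise tests) -- plus `manifest.json` and
#' `run.log`. Machine tables carry full precision; display variants are
#' rounded to 2 decimals. On error all partially written files of this run
#' are removed.
#'
#' @param study a `faers_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("study failed at stage 'write': %s", conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    wr <- function(df, name) {
      path <- file.path(dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                         row.names = FALSE)
      written <<- c(written, path)
    }

    t3 <- do.call(rbind, lapply(names(study$cohort_summaries), function(d) {
      s <- study$cohort_summaries[[d]]
      blocks <- rbind(
        cbind(block = "age", s$age_strata),
        cbind(block = "sex", s$sex_counts),
        cbind(block = "country", s$country_counts),
        cbind(block = "year_period", s$year_period_counts))
      cbind(drug = d, n_total = s$n_total, blocks,
            age_mean = s$age_mean, age_sd = s$age_sd)
    }))
    wr(t3, "table3_characteristics.tsv")

    t4 <- do.call(rbind, lapply(names(study$contexts), function(d) {
      ctx <- study$contexts[[d]]
      do.call(rbind, lapply(names(ctx), function(b) {
        if (nrow(ctx[[b]]) == 0) return(NULL)
        cbind(drug = d, block = b, ctx[[b]])
      }))
    }))
    wr(t4 %||% data.frame(), "table4_context.tsv")

    wr(study$signals, "table5_smq_signals.tsv")
    wr(format_signal_table(study$signals), "table5_smq_signals_display.tsv")

    t6 <- do.call(rbind, lapply(names(study$pt_signals), function(d) {
      df <- study$pt_signals[[d]]
      if (nrow(df) == 0) NULL else df
    }))
    if (is.null(t6)) {
      t6 <- data.frame(term = character(), drug = character(),
                       n = integer())
    }
    wr(t6, "table6_pt_signals.tsv")
    if (nrow(t6) > 0) {
      disp6 <- cbind(term = t6$term, format_signal_table(t6))
    } else {
      disp6 <- t6
    }
    wr(disp6, "table6_pt_signals_display.tsv")

    wr(study$outcome_rates, "fig2_outcomes.tsv")
    if (!is.null(study$outcome_comparisons)) {
      tests <- do.call(rbind, lapply(study$outcome_comparisons, function(cmp) {
        cbind(outcome = cmp$outcome, omnibus_p = cmp$omnibus_p,
              omnibus_test = cmp$omnibus_test, cmp$pairwise)
      }))
      rownames(tests) <- NULL
      wr(tests, "fig2_outcome_tests.tsv")
    }

    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(study$manifest, mpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, mpath)
    lpath <- file.path(dir, "run.log")
    writeLines(c(study$log,
                 sprintf("stage counts: loaded=%d deduplicated=%d",
                         study$manifest$stage_counts$loaded,
                         study$manifest$stage_counts$deduplicated)), lpath)
    written <- c(written, lpath)
    invisible(written)
  }, error = on_fail)
}

#' Bar chart of per-outcome report rates
#'
#' Presentation helper: grouped bars of the outcome rates per drug, one
#' group per outcome category.
#'
#' @param x a `faers_study`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the rate matrix plotted.
#' @export
plot.faers_study <- function(x, ...) {
  r <- x$outcome_rates
  m <- tapply(r$rate, list(r$drug, r$outcome), identity)
  m <- m[, intersect(outcome_levels(), colnames(m)), drop = FALSE]
  graphics::barplot(100 * m, beside = TRUE, legend.text = rownames(m),
                    ylab = "reports with outcome (%)",
                    las = 2, cex.names = 0.8, ...)
  invisible(m)
}
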