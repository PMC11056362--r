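default_events <- function() {
  data.frame(
    pt_code = c(10043882L, 10011878L, 10048865L, 10061373L, 10048812L),
    term = c("Tinnitus", "Deafness", "Hypoacusis", "Sudden hearing loss",
             "Deafness unilateral"),
    baseline = c(0.020, 0.010, 0.015, 0.004, 0.003),
    stringsAsFactors = FALSE)
}

default_background_events <- function() {
  data.frame(
    pt_code = c(10013709L, 10019211L, 10013573L, 10028813L, 10013968L),
    term = c("Drug ineffective", "Headache", "Dizziness", "Nausea",
             "Dyspnoea"),
    baseline = c(0.10, 0.12, 0.08, 0.08, 0.05),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic report generator
#'
#' Bundles every knob of the generative model, with defaults emulating a
#' spontaneous-reporting slice centred on erectile-dysfunction /
#' pulmonary-hypertension drugs and hearing-related adverse events: a few
#' declared drugs with small primary-suspect marginals against a background
#' drug universe, hearing-impairment PTs at sub-percent to percent baseline
#' reporting probabilities plus common background PTs (headache, dizziness,
#' ...), elderly-male-skewed demographics with substantial missing age
#' (unknown age runs near 40% in such case series), US-dominated reporting
#' countries over 2003-2023, severity-outcome probabilities, case-level
#' near-duplicates, and planted drug-event reporting-rate ratios (the
#' ground truth for recovery tests; 1 = null).
#'
#' @param n_reports number of logical reports (duplicates come on top).
#' @param drugs named numeric vector: per-drug marginal probability of
#'   being a report's primary suspect; must sum to <= 1, the remainder is
#'   spread uniformly over the background drug pool.
#' @param background_drug_pool size of the "other drugs" universe.
#' @param events data frame (`pt_code`, `term`, `baseline`): declared
#'   events, included per report with probability
#'   `min(1, baseline * rr(drug, pt))`.
#' @param background_events same layout; never signal-tested. The first one
#'   doubles as filler so every report has at least one reaction.
#' @param planted_rr data frame (`drug`, `pt_code`, `rr`): relative
#'   reporting-rate ratios >= 0 for declared (drug, event) pairs; absent
#'   pairs default to 1.
#' @param co_drug_rate expected number of non-primary co-medication entries
#'   per report (Poisson).
#' @param demographics list with `age_mean`, `age_sd`, `male_fraction`,
#'   `country_probs` (named, sums to 1), `year_range`, and optionally
#'   `per_drug`, a named list of per-drug overrides of the first three.
#' @param outcome_probs named per-outcome probabilities.
#' @param p_missing_age,p_missing_sex missingness probabilities.
#' @param p_duplicate probability a report is emitted twice under one
#'   `case_id` (the copy gets a later `report_id` and a re-drawn country,
#'   so deduplication is exercised on near-duplicates).
#' @param seed integer root seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_reports = 10000,
                         drugs = c(sildenafil = 0.030, vardenafil = 0.008,
                                   tadalafil = 0.020, avanafil = 0.002),
                         background_drug_pool = 40,
                         events = default_events(),
                         background_events = default_background_events(),
                         planted_rr = NULL,
                         co_drug_rate = 1.2,
                         demographics = list(),
                         outcome_probs = c(hospitalization = 0.08,
                                           disability = 0.09,
                                           life_threatening = 0.02,
                                           death = 0.02,
                                           required_intervention = 0.04,
                                           other = 0.25),
                         p_missing_age = 0.40, p_missing_sex = 0.05,
                         p_duplicate = 0.05, seed = 1L) {
  demo_default <- list(
    age_mean = 60, age_sd = 13, male_fraction = 0.8,
    country_probs = c(US = 0.80, CA = 0.05, GB = 0.05, JP = 0.03, BR = 0.02,
                      DE = 0.05),
    year_range = c(2003L, 2023L), per_drug = list())
  demographics <- utils::modifyList(demo_default, demographics)

  stopifnot(n_reports >= 1)
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    stop("drugs must be a named vector of marginals", call. = FALSE)
  }
  names(drugs) <- normalize_drug_name(names(drugs))
  if (any(drugs < 0) || sum(drugs) > 1 + 1e-12) {
    stop("drug marginals must be >= 0 and sum to <= 1", call. = FALSE)
  }
  events <- as.data.frame(events)
  background_events <- as.data.frame(background_events)
  for (df in list(events, background_events)) {
    stopifnot(all(c("pt_code", "term", "baseline") %in% names(df)),
              all(df$baseline >= 0 & df$baseline <= 1))
  }
  probs <- c(outcome_probs, p_missing_age, p_missing_sex, p_duplicate,
             demographics$country_probs, demographics$male_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(planted_rr)) {
    planted_rr <- as.data.frame(planted_rr)
    stopifnot(all(c("drug", "pt_code", "rr") %in% names(planted_rr)))
    planted_rr$drug <- normalize_drug_name(planted_rr$drug)
    if (!all(planted_rr$drug %in% names(drugs))) {
      stop("planted_rr references undeclared drug(s)", call. = FALSE)
    }
    if (!all(planted_rr$pt_code %in% events$pt_code)) {
      stop("planted_rr references undeclared event(s)", call. = FALSE)
    }
    if (any(planted_rr$rr < 0)) stop("rr must be >= 0", call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 background_drug_pool = as.integer(background_drug_pool),
                 events = events, background_events = background_events,
                 planted_rr = planted_rr, co_drug_rate = co_drug_rate,
                 demographics = demographics, outcome_probs = outcome_probs,
                 p_missing_age = p_missing_age, p_missing_sex = p_missing_sex,
                 p_duplicate = p_duplicate, seed = as.integer(seed)),
            class = "synth_config")
}

# drug universe and marginals implied by a config
drug_pool <- function(config) {
  bg <- sprintf("bgdrug%02d", seq_len(config$background_drug_pool))
  pool <- c(names(config$drugs), bg)
  rem <- max(0, 1 - sum(config$drugs))
  probs <- c(unname(config$drugs), rep(rem / length(bg), length(bg)))
  list(names = pool, probs = probs)
}

# per-pool-drug inclusion probability for one declared event, clamped at 1
event_prob_by_drug <- function(config, pt_code, pool_names) {
  base <- config$events$baseline[config$events$pt_code == pt_code]
  rr <- rep(1, length(pool_names))
  pr <- config$planted_rr
  if (!is.null(pr)) {
    hit <- pr[pr$pt_code == pt_code, , drop = FALSE]
    rr[match(hit$drug, pool_names)] <- hit$rr
  }
  pmin(1, base * rr)
}

#' Generate a synthetic report collection
#'
#' Draws `n_reports` logical reports from the generative model in
#' [synth_config()]: a primary-suspect drug from the marginals; each
#' declared event independently with probability
#' `min(1, baseline * rr(drug, pt))` (infeasible products warn and are
#' clamped, recorded in the generation log); background events at their
#' baselines; Poisson co-medications; per-drug demographics with
#' missingness; outcome codes; and case-level near-duplicates (same
#' `case_id`, later `report_id`, re-drawn country). The same seed yields an
#' identical collection. The caller's RNG state is left untouched.
#'
#' @param config a `synth_config`.
#' @param seed overrides `config$seed` if given.
#' @return a `report_collection` (run [deduplicate()] before analysis).
#' @export
generate_reports <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- seed %||% config$seed
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  log <- character()

  n <- config$n_reports
  pool <- drug_pool(config)
  primary_idx <- sample.int(length(pool$names), n, replace = TRUE,
                            prob = pool$probs)
  primary <- pool$names[primary_idx]
  rid <- sprintf("R%07d", seq_len(n))
  cid <- sprintf("C%07d", seq_len(n))

  ## reactions: declared events (drug-dependent), then background events
  reac_rid <- character(0); reac_code <- integer(0); reac_term <- character(0)
  for (k in seq_len(nrow(config$events))) {
    pt <- config$events$pt_code[k]
    p_by_drug <- event_prob_by_drug(config, pt, pool$names)
    req <- config$events$baseline[k] *
      max(1, if (is.null(config$planted_rr)) 1 else
        config$planted_rr$rr[config$planted_rr$pt_code == pt])
    if (req > 1) {
      warning(sprintf("event %d: baseline x rr = %.3g > 1, clamped", pt, req),
              call. = FALSE)
      log <- c(log, sprintf("clamped inclusion probability for PT %d", pt))
    }
    hit <- which(stats::runif(n) < p_by_drug[primary_idx])
    reac_rid <- c(reac_rid, rid[hit])
    reac_code <- c(reac_code, rep(pt, length(hit)))
    reac_term <- c(reac_term, rep(config$events$term[k], length(hit)))
  }
  for (k in seq_len(nrow(config$background_events))) {
    hit <- which(stats::runif(n) < config$background_events$baseline[k])
    reac_rid <- c(reac_rid, rid[hit])
    reac_code <- c(reac_code, rep(config$background_events$pt_code[k],
                                  length(hit)))
    reac_term <- c(reac_term, rep(config$background_events$term[k],
                                  length(hit)))
  }
  # every report needs >= 1 reaction: pad with the filler background PT
  bare <- setdiff(rid, reac_rid)
  if (length(bare)) {
    reac_rid <- c(reac_rid, bare)
    reac_code <- c(reac_code, rep(config$background_events$pt_code[1],
                                  length(bare)))
    reac_term <- c(reac_term, rep(config$background_events$term[1],
                                  length(bare)))
  }

  ## drug entries: the primary suspect plus Poisson co-medications
  dose_opts <- c("100 mg, once", "50 mg, once", "20 mg, once", "10 mg, once",
                 "5 mg, once", "20 mg, tid")
  ind_opts <- c("Erectile dysfunction", "Pulmonary arterial hypertension",
                "Benign prostatic hyperplasia", "Hypertension")
  drug_rid <- rid
  drug_name <- primary
  drug_role <- rep("primary_suspect", n)
  drug_dose <- sample(dose_opts, n, replace = TRUE)
  drug_ind <- sample(ind_opts, n, replace = TRUE)
  m_co <- stats::rpois(n, config$co_drug_rate)
  if (sum(m_co) > 0) {
    co_rid <- rep(rid, m_co)
    co_name <- sample(pool$names, sum(m_co), replace = TRUE)
    drug_rid <- c(drug_rid, co_rid)
    drug_name <- c(drug_name, co_name)
    drug_role <- c(drug_role, rep("concomitant", sum(m_co)))
    drug_dose <- c(drug_dose, rep(NA_character_, sum(m_co)))
    drug_ind <- c(drug_ind, rep(NA_character_, sum(m_co)))
  }

  ## demographics, with per-drug overrides for declared drugs
  dg <- config$demographics
  par_for <- function(field, default) {
    v <- rep(default, n)
    for (d in names(dg$per_drug)) {
      ov <- dg$per_drug[[d]][[field]]
      if (!is.null(ov)) v[primary == normalize_drug_name(d)] <- ov
    }
    v
  }
  age <- stats::rnorm(n, par_for("age_mean", dg$age_mean),
                      par_for("age_sd", dg$age_sd))
  age <- pmin(100, pmax(18, age))
  age[stats::runif(n) < config$p_missing_age] <- NA_real_
  sex <- ifelse(stats::runif(n) < par_for("male_fraction", dg$male_fraction),
                "male", "female")
  sex[stats::runif(n) < config$p_missing_sex] <- "unknown"
  country <- sample(names(dg$country_probs), n, replace = TRUE,
                    prob = dg$country_probs)
  year <- sample(seq(dg$year_range[1], dg$year_range[2]), n, replace = TRUE)

  ## outcomes
  outc_rid <- character(0); outc_val <- character(0)
  for (oc in names(config$outcome_probs)) {
    hit <- which(stats::runif(n) < config$outcome_probs[[oc]])
    outc_rid <- c(outc_rid, rid[hit])
    outc_val <- c(outc_val, rep(oc, length(hit)))
  }

  ## near-duplicates: same case, later report_id, country re-drawn
  dup <- which(stats::runif(n) < config$p_duplicate)
  demo <- data.frame(report_id = rid, case_id = cid, age = age, sex = sex,
                     country = country, year = year, stringsAsFactors = FALSE)
  if (length(dup)) {
    dup_rid <- paste0(rid[dup], "D")
    demo2 <- demo[dup, , drop = FALSE]
    demo2$report_id <- dup_rid
    demo2$country <- sample(names(dg$country_probs), length(dup),
                            replace = TRUE, prob = dg$country_probs)
    demo <- rbind(demo, demo2)
    dup_rows <- function(ids, ...) {
      sel <- ids %in% rid[dup]
      idx <- match(ids[sel], rid[dup])
      list(sel = sel, rid = dup_rid[idx])
    }
    dr <- dup_rows(drug_rid)
    drug_rid <- c(drug_rid, dr$rid)
    drug_name <- c(drug_name, drug_name[dr$sel])
    drug_role <- c(drug_role, drug_role[dr$sel])
    drug_dose <- c(drug_dose, drug_dose[dr$sel])
    drug_ind <- c(drug_ind, drug_ind[dr$sel])
    rr <- dup_rows(reac_rid)
    reac_rid <- c(reac_rid, rr$rid)
    reac_code <- c(reac_code, reac_code[rr$sel])
    reac_term <- c(reac_term, reac_term[rr$sel])
    oc <- dup_rows(outc_rid)
    outc_rid <- c(outc_rid, oc$rid)
    outc_val <- c(outc_val, outc_val[oc$sel])
    log <- c(log, sprintf("emitted %d duplicate report(s)", length(dup)))
  }

  report_collection(
    demo = demo,
    drugs = data.frame(report_id = drug_rid, drug_name = drug_name,
                       role = drug_role, dose_text = drug_dose,
                       indication_pt = drug_ind, stringsAsFactors = FALSE),
    reactions = data.frame(report_id = reac_rid, pt_code = reac_code,
                           pt_term = reac_term, stringsAsFactors = FALSE),
    outcomes = data.frame(report_id = outc_rid, outcome = outc_val,
                          stringsAsFactors = FALSE),
    provenance = sprintf("synthetic (seed %d, n_reports %d)", seed, n),
    log = log
  )
}

#' Expected disproportionality under the generative model
#'
#' Closed-form expected 2x2 cell proportions and the implied true ROR, PRR
#' and IC for every declared (drug, event) pair, for use in parameter
#' recovery tests. Clamped inclusion probabilities are reflected in
#' `rr_effective`, keeping the truth consistent with [generate_reports()].
#'
#' @param config a `synth_config`.
#' @return data frame with one row per declared pair: `drug`, `pt_code`,
#'   `term`, `rr`, `rr_effective`, `p_a`, `p_b`, `p_c`, `p_d`, `true_ror`,
#'   `true_prr`, `true_ic`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  pool <- drug_pool(config)
  rows <- list()
  for (g in names(config$drugs)) {
    pi_g <- pool$probs[match(g, pool$names)]
    for (k in seq_len(nrow(config$events))) {
      pt <- config$events$pt_code[k]
      base <- config$events$baseline[k]
      p_by_drug <- event_prob_by_drug(config, pt, pool$names)
      p_e_g <- p_by_drug[match(g, pool$names)]
      p_a <- pi_g * p_e_g
      p_b <- sum(pool$probs * p_by_drug) - p_a
      p_c <- pi_g - p_a
      p_d <- 1 - p_a - p_b - p_c
      rr_req <- if (is.null(config$planted_rr)) 1 else {
        hit <- config$planted_rr$drug == g & config$planted_rr$pt_code == pt
        if (any(hit)) config$planted_rr$rr[hit][1] else 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug = g, pt_code = pt, term = config$events$term[k],
        rr = rr_req, rr_effective = p_e_g / base,
        p_a = p_a, p_b = p_b, p_c = p_c, p_d = p_d,
        true_ror = (p_a * p_d) / (p_b * p_c),
        true_prr = (p_a / (p_a + p_c)) / (p_b / (p_b + p_d)),
        true_ic = log2(p_a / ((p_a + p_b) * (p_a + p_c))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a generator configuration as YAML
#'
#' The flat key/value + list layout of [synth_config()] serialized with
#' `yaml`. `read_synth_config()` revalidates through the constructor.
#'
#' @param path file path.
#' @return `read_synth_config`: a `synth_config`.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(z) if (is.null(z)) NULL else
    do.call(rbind, lapply(z, as.data.frame))
  args <- list(
    n_reports = y$n_reports,
    drugs = unlist(y$drugs),
    background_drug_pool = y$background_drug_pool %||% 40,
    co_drug_rate = y$co_drug_rate %||% 1.2,
    p_missing_age = y$p_missing_age %||% 0.40,
    p_missing_sex = y$p_missing_sex %||% 0.05,
    p_duplicate = y$p_duplicate %||% 0.05,
    seed = y$seed %||% 1L)
  if (!is.null(y$events)) args$events <- to_df(y$events)
  if (!is.null(y$background_events)) {
    args$background_events <- to_df(y$background_events)
  }
  if (!is.null(y$planted_rr)) args$planted_rr <- to_df(y$planted_rr)
  if (!is.null(y$demographics)) {
    d <- y$demographics
    if (!is.null(d$country_probs)) d$country_probs <- unlist(d$country_probs)
    if (!is.null(d$year_range)) d$year_range <- unlist(d$year_range)
    args$demographics <- d
  }
  if (!is.null(y$outcome_probs)) args$outcome_probs <- unlist(y$outcome_probs)
  do.call(synth_config, args)
}

#' @rdname read_synth_config
#' @param config a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  df_to_list <- function(df) if (is.null(df)) NULL else
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  demo <- config$demographics
  demo$country_probs <- as.list(demo$country_probs)  # keep names in YAML
  y <- list(
    n_reports = config$n_reports, drugs = as.list(config$drugs),
    background_drug_pool = config$background_drug_pool,
    events = df_to_list(config$events),
    background_events = df_to_list(config$background_events),
    planted_rr = df_to_list(config$planted_rr),
    co_drug_rate = config$co_drug_rate,
    demographics = demo,
    outcome_probs = as.list(config$outcome_probs),
    p_missing_age = config$p_missing_age,
    p_missing_sex = config$p_missing_sex,
    p_duplicate = config$p_duplicate, seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
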