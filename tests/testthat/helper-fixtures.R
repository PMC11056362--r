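# Fixture builders and independent oracles shared across test files.

# Build a report_collection from a compact list-of-reports description.
# Each report: list(id, case = id, drugs = named chr (name -> role),
#   pts = integer codes, terms = optional chr parallel to pts,
#   age = NA, sex = "male", country = "US", year = 2015, outcomes = chr())
mk_collection <- function(reports) {
  demo <- do.call(rbind, lapply(reports, function(r) {
    data.frame(report_id = r$id, case_id = r$case %||% r$id,
               age = r$age %||% NA_real_, sex = r$sex %||% "male",
               country = r$country %||% "US", year = r$year %||% 2015L,
               stringsAsFactors = FALSE)
  }))
  drugs <- do.call(rbind, lapply(reports, function(r) {
    data.frame(report_id = r$id, drug_name = names(r$drugs),
               role = unname(r$drugs), dose_text = NA_character_,
               indication_pt = NA_character_, stringsAsFactors = FALSE)
  }))
  reactions <- do.call(rbind, lapply(reports, function(r) {
    terms <- r$terms %||% rep(NA_character_, length(r$pts))
    data.frame(report_id = r$id, pt_code = r$pts, pt_term = terms,
               stringsAsFactors = FALSE)
  }))
  outcomes <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$outcomes) || !length(r$outcomes)) return(NULL)
    data.frame(report_id = r$id, outcome = r$outcomes,
               stringsAsFactors = FALSE)
  }))
  report_collection(demo, drugs, reactions, outcomes,
                    provenance = "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A cohort with prescribed age-stratum counts (representative ages per bin);
# all primary-suspect reports for one drug with one SMQ reaction each.
cohort_from_strata <- function(le44, s4559, s6074, ge75, unknown,
                               drug = "sildenafil") {
  ages <- c(rep(40, le44), rep(50, s4559), rep(65, s6074), rep(80, ge75),
            rep(NA_real_, unknown))
  n <- length(ages)
  ids <- sprintf("R%04d", seq_len(n))
  report_collection(
    demo = data.frame(report_id = ids, case_id = ids, age = ages,
                      sex = "male", country = "US", year = 2015L,
                      stringsAsFactors = FALSE),
    drugs = data.frame(report_id = ids, drug_name = drug,
                       role = "primary_suspect", dose_text = NA_character_,
                       indication_pt = NA_character_,
                       stringsAsFactors = FALSE),
    reactions = data.frame(report_id = ids, pt_code = 10043882L,
                           pt_term = "Tinnitus", stringsAsFactors = FALSE))
}

# Write the four delimited fixture tables used by the reader tests; returns
# the named path vector. 3 demographics rows, 5 drug rows (one orphan),
# 4 reaction rows.
write_fixture_tables <- function(dir, sep = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, lines) {
    path <- file.path(dir, name)
    writeLines(gsub("\\|", sep, lines, fixed = FALSE), path)
    path
  }
  c(demo = w("demo.txt", c(
      "report_id|case_id|age|sex|country|year",
      "R1|C1|61|M|US|2010",
      "R2|C2|abc|F|CA|2015",
      "R3|C3||unknown|GB|2020")),
    drug = w("drug.txt", c(
      "report_id|drug_name|role_code|dose|indication",
      "R1|Sildenafil |PS|100 mg once|Erectile dysfunction",
      "R1|warfarin|C||",
      "R2|tadalafil|PS|20 mg once|",
      "R3|sildenafil|PS||",
      "R9|ghostdrug|PS||")),
    reac = w("reac.txt", c(
      "report_id|pt_code|pt_term",
      "R1|10043882|Tinnitus",
      "R2|10048865|Hypoacusis",
      "R2|10019211|Headache",
      "R3||Tinnitus")),
    outc = w("outc.txt", c(
      "report_id|outcome_code",
      "R1|HO",
      "R2|DS",
      "R2|DE")))
}

# Independently coded textbook Pearson chi-squared on a 2x2 (all four cells).
chi2_oracle <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value
# (sum of all outcome probabilities <= the observed table's), via choose().
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - r2):min(r1, c1)
  p <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Random non-degenerate 2x2 cell draws for property tests.
rand_cells <- function(k, lo = 1, hi = 1e4) {
  matrix(sample(lo:hi, 4 * k, replace = TRUE), ncol = 4,
         dimnames = list(NULL, c("a", "b", "c", "d")))
}
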