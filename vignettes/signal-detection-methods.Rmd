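---
title: "Disproportionality signal detection: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem and the model

Spontaneous reporting systems collect voluntary reports that associate one
or more drugs with one or more adverse events in a patient, but carry no
information about how many patients took each drug without incident. Signal
detection therefore works *within* the database: for a drug $D$ and an
event definition $E$, the deduplicated report collection is partitioned
into the 2×2 table $(a, b, c, d)$ — $a$ reports with $D$ as primary
suspect and $E$; $b$ with $E$ under other drugs; $c$ with $D$ and other
events; $d$ with neither — and the question becomes whether $a$ exceeds
what the margins predict. The comparator universe for $b$ and $d$ is the
entire ingested collection, i.e. all other medications.

Three estimators are computed on this table.

**ROR.** The reporting odds ratio $(a/b)/(c/d)$ with the Woolf-type
interval $\exp(\ln \mathrm{ROR} \pm 1.96\,s)$,
$s = \sqrt{1/a + 1/b + 1/c + 1/d}$. The interval is symmetric on the log
scale, so $\mathrm{ROR} = \sqrt{\text{low} \times \text{high}}$ — an
identity the test suite checks both on random tables and on published
signal rows. Positivity: CI lower bound $> 1$ and $N \ge 2$, where $N$ is
the co-occurrence count $a$ throughout.

**PRR.** The proportional reporting ratio
$(a/(a+c)) / (b/(b+d))$, paired with Pearson's $\chi^2$. Some published
formulations spell out only the $a$-cell term of the statistic; the sum
sign implies all four cells, and the package defaults to the standard
four-cell statistic (`chi2_mode = "all_cells"`), retaining
`"a_cell_only"` as a literal-reading switch. $\chi^2$ is computed on raw
counts with no continuity correction by default; a Yates flag exists
because conventions differ. Positivity: $\mathrm{PRR} \ge 2$,
$\chi^2 \ge 4$, $N \ge 3$.

**BCPNN IC.** The information component
$\mathrm{IC} = \log_2 \frac{aN}{(a+c)(a+b)}$ measures observed-to-expected
co-reporting. Its lower 95% limit is evaluated *multiplicatively*,
$\mathrm{IC025} = \exp(\ln \mathrm{IC} - 1.96\,s)$, the form that is
self-consistent with the published signal tables this package mirrors
(e.g. an IC pair of 1.48 and 1.37 at large counts satisfies it to the
printed precision). Classical BCPNN instead uses a posterior credible
interval; an additive approximation (`ic_mode = "ic_minus_2sd"`,
$\mathrm{IC} - 1.96\,s$ on the log2 scale) is provided but off by default.

A pair is a positive signal when **any** of the three criteria is met.

### A consequence of the multiplicative IC025 worth knowing

Algebraically $\mathrm{IC} > 0 \iff ad > bc \iff \mathrm{ROR} > 1$, and
$\exp(\cdot)$ is strictly positive wherever it is evaluable. Under the
multiplicative form the BCPNN criterion "IC025 > 0" therefore fires for
*every* table whose ROR point estimate exceeds 1, regardless of
uncertainty — it is the most permissive of the three rules, and the
any-of-three signal inherits that permissiveness (a pair with
ROR 1.12, CI 0.74–1.68 is still BCPNN-positive). For $\mathrm{IC} \le 0$
the limit is not evaluable ($\ln$ of a non-positive number) and the
criterion cannot fire. The additive mode restores the conventional,
uncertainty-aware behaviour; the test suite demonstrates both, including a
small-table configuration that is positive through the ROR rule alone
under the additive mode — a configuration that provably cannot exist under
the multiplicative form.

## Numerical choices

- **Zero cells.** Any zero cell triggers the Haldane–Anscombe correction:
  $+0.5$ on all four cells for ROR, PRR and IC point and interval
  estimates, flagged in the result. $\chi^2$ stays on raw counts, so the
  test statistic is not distorted; if a raw margin is zero the statistic
  is degenerate and reported as 0 with a flag. No estimator ever returns
  an infinity.
- **Deduplication.** One report per case identifier is retained — the
  lexicographically greatest `report_id`, a deterministic proxy for the
  most recent case version (later versions supersede earlier ones in
  FAERS practice). The operation is idempotent and preserves the set of
  case identifiers. Which version to keep was a genuinely open choice;
  determinism and the versioning convention decided it.
- **Rounding.** Displayed percentages and two-decimal tables use half-up
  rounding (`round_half_up()`), not banker's rounding, so outputs are
  platform-stable and match how case-series tables are conventionally
  printed. Percentages use the full cohort (unknowns included) as
  denominator.
- **Event matching.** SMQ membership is decided by numeric PT code when
  present, falling back to case-insensitive exact term match; no fuzzy or
  substring matching, for reproducibility over recall. The counting unit
  is the report: a report with several member PTs counts once at SMQ
  level but once per PT in breakdowns.
- **Fisher/χ² switch.** Outcome-rate comparisons use Fisher's exact test
  (two-sided, sum of all hypergeometric outcomes no more probable than
  the observed table) when any expected cell is below 5, else Pearson's
  χ² without continuity correction; the boundary case (expected exactly
  5) goes to χ², the usual convention. Bonferroni correction is applied
  per outcome category across its pairwise tests — multiplying by the
  number of pairs actually performed after excluding empty cohorts — not
  across outcome categories.
- **Age strata.** Bins are ≤44 (meaning age < 45), 45–59, 60–74, ≥75 and
  unknown; the mean and the $n-1$ sample SD are computed over known ages
  only. Reporting years outside 2003–2023 fall into an "other" period
  rather than erroring.

## The synthetic report generator

`synth_config()` / `generate_reports()` emulate the structure of a
FAERS-style slice so every pipeline stage is testable without external
data: a handful of declared drugs with small primary-suspect marginals
(defaults 3%, 2%, 0.8%, 0.2%) against a 40-drug background universe;
hearing-impairment PTs at 0.3–2% baseline per-report probabilities plus
common background PTs (headache, dizziness, nausea, ...); Poisson
co-medications (mean 1.2/report); elderly-male-skewed demographics (age
mean 60, SD 13, 80% male) with 40% missing age — matching the roughly
40–48% unknown-age fraction such case series show — and 5% missing sex;
US-dominated reporting countries; uniform reporting years 2003–2023;
per-outcome severity probabilities; and 5% case-level near-duplicates
(same case, later report id, re-drawn country, so deduplication is
exercised on non-identical copies). These defaults are the package's
study conditions and were chosen once, on field plausibility.

The key knob is `planted_rr`: a declared (drug, event) pair is included
with probability $\min(1, \text{baseline} \times rr)$, so the generative
model has closed-form cell probabilities. `truth_table()` evaluates them
exactly — including the clamping at probability 1, which it reports as an
effective ratio — and yields the true ROR, PRR and IC for recovery tests.
Under the rare-event regime the true ROR slightly exceeds the planted
$rr$ while the true PRR equals it exactly (events are conditionally
independent given the drug, so the comparator rate is the baseline).

Randomness is driven by one `set.seed()` per generation with draws in a
fixed field order: the same seed yields a byte-identical collection, and
the caller's RNG state is restored afterwards. The draws are vectorized
over reports rather than split into one stream per report; the
determinism contract holds, but appending reports to a configuration does
reshuffle earlier ones — a deliberate trade for the throughput the
replicated calibration suites need.

What the generator does *not* emulate: secular reporting trends, MedDRA
version drift, reporter types, correlated event clusters, or
drug-specific outcome profiles beyond the configured probabilities.
Passing recovery tests therefore shows the estimators and pipeline are
correct under conditional independence and stationarity — not that real
FAERS data meet those assumptions.

## Validation design and problem sizes

The suite separates implementation from oracle everywhere: $\chi^2$
against an independently coded textbook statistic (and `stats::chisq.test`)
on 1,000 random tables; ROR/PRR/IC against direct formula evaluation;
Fisher's exact (delegated to `stats::fisher.test` in the comparison path)
against exhaustive hypergeometric enumeration via binomial coefficients on
hundreds of sampled tables with cells ≤ 30; interval calibration on 500
draws from a known-odds-ratio binomial model (coverage required in
92–98%); null calibration on 500 seeded synthetic replicates sized for an
expected co-occurrence count of 20 (the full PRR criterion must fire in
under 5%); planted-ratio recovery at $rr \in \{2, 5, 10\}$ over 500
replicates each, sized for expected $a \ge 30$; and an end-to-end check
that a sixfold planted pair is flagged by the any-of-three rule in at
least 95% of 100 studies of 20,000 reports. These sizes were chosen to
put Monte-Carlo error well inside the asserted bands while keeping the
default test run in minutes on a single core.

## Known limitations

- Disproportionality quantifies reporting association, not risk or
  causation; no confounding adjustment is attempted.
- The multiplicative IC025 (see above) makes the combined positivity rule
  behave essentially like "ROR point estimate > 1 or PRR criterion or ROR
  CI criterion"; users wanting the conservative BCPNN behaviour should
  set `ic_mode = "ic_minus_2sd"`.
- Drug-name normalization is exact-match (lowercase, trimmed, optional
  synonym map); misspelled or free-text drug names in real extracts will
  not be merged.
- The packaged SMQ is the single narrow-scope hearing-impairment set; no
  MedDRA hierarchy navigation or broad-scope algorithmic terms.
- Duplicate detection is by case identifier only; true duplicates filed
  under different case numbers survive deduplication, as in the source
  systems.
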