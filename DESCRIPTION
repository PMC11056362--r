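Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pharmacovigilance signal-detection pipeline for FAERS-style
    spontaneous adverse event report tables. Ingests the four-table quarterly
    layout (demographics, drugs, reactions, outcomes), deduplicates reports by
    case identifier, classifies adverse events with MedDRA standardized query
    (SMQ) preferred-term sets, builds drug-event 2x2 contingency tables and
    computes three disproportionality statistics -- the reporting odds ratio
    (ROR), the proportional reporting ratio (PRR) with its Pearson chi-squared
    statistic, and the Bayesian confidence propagation neural network
    information component (IC) -- together with their positivity criteria.
    Also provides stratified cohort descriptives, outcome-rate comparisons with
    Bonferroni-corrected chi-square/Fisher tests, and a synthetic report
    generator with planted, analytically known reporting-rate ratios for
    end-to-end validation. Ships the 56-term narrow SMQ for hearing impairment
    as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
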