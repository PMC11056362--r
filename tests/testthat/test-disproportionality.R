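test_that("contingency construction partitions the collection by drug role and event", {
  # hand-enumerated 6-report fixture; concomitant X must not count toward a
  coll <- mk_collection(list(
    list(id = "R1", drugs = c(x = "primary_suspect"), pts = 1L),          # a
    list(id = "R2", drugs = c(x = "primary_suspect"), pts = 2L),          # c
    list(id = "R3", drugs = c(y = "primary_suspect"), pts = 1L),          # b
    list(id = "R4", drugs = c(y = "primary_suspect"), pts = 2L),          # d
    list(id = "R5", drugs = c(y = "primary_suspect"), pts = 1L),          # b
    list(id = "R6", drugs = c(y = "primary_suspect", x = "concomitant"),
         pts = 1L)))                                                      # b
  tab <- build_contingency(coll, "x", 1)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 3, 1, 1))
  expect_equal(tab$n_total, n_reports(coll))

  # drug absent: empty drug margin
  tab0 <- build_contingency(coll, "absent", 1)
  expect_equal(c(tab0$a, tab0$c), c(0, 0))
  expect_equal(tab0$a + tab0$b + tab0$c + tab0$d, 6)

  empty <- mk_collection(list(
    list(id = "R1", drugs = c(x = "primary_suspect"), pts = 1L)))
  expect_error(build_contingency(filter_primary_suspect(empty, "nope"),
                                 "x", 1), "empty collection")
})

test_that("ROR, PRR, chi-squared and IC match hand-evaluated formulas", {
  # independence: all measures at their null
  ind <- contingency_table(10, 90, 90, 810)
  expect_equal(compute_ror(ind)$ror, 1)
  expect_equal(compute_ic(ind)$ic, 0)
  ind2 <- contingency_table(10, 20, 90, 180)
  p <- compute_prr(ind2)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  # hand evaluation at a=5, b=5, c=5, d=45
  tab <- contingency_table(5, 5, 5, 45)
  r <- compute_ror(tab)
  expect_equal(r$ror, 9)
  expect_equal(r$ci_low, 9 * exp(-1.96 * sqrt(1/5 + 1/5 + 1/5 + 1/45)))
  expect_equal(round(r$ci_low, 2), 1.92)
  expect_equal(round(r$ci_high, 1), 42.2)
  p <- compute_prr(tab)
  expect_equal(p$prr, 5)
  expect_equal(p$chi2, 9.6)  # four-cell sum 6.667 + 1.333 + 1.333 + 0.267
  ic <- compute_ic(tab)
  expect_equal(ic$ic, log2(3))
  expect_equal(round(ic$ic025, 3), 0.338)

  # a-cell-only chi-squared mode is the literal single-term reading
  expect_equal(compute_prr(tab, chi2_mode = "a_cell_only")$chi2,
               (5 - 10 * 10 / 60)^2 / (10 * 10 / 60))
})

test_that("statistics match independent oracles on 1000 random tables", {
  set.seed(101)
  cells <- rand_cells(1000)
  for (i in seq_len(nrow(cells))) {
    a <- unname(cells[i, 1]); b <- unname(cells[i, 2])
    c <- unname(cells[i, 3]); d <- unname(cells[i, 4])
    tab <- contingency_table(a, b, c, d)
    expect_equal(compute_prr(tab)$chi2, chi2_oracle(a, b, c, d),
                 tolerance = 1e-9)
    expect_equal(compute_ror(tab)$ror, (a / b) / (c / d), tolerance = 1e-12)
    expect_equal(compute_prr(tab)$prr, (a / (a + c)) / (b / (b + d)),
                 tolerance = 1e-12)
    expect_equal(compute_ic(tab)$ic,
                 log2(a * (a + b + c + d) / ((a + c) * (a + b))),
                 tolerance = 1e-12)
  }
  # and chi2 equals the stats:: reference on a spot sample
  for (i in sample(nrow(cells), 25)) {
    m <- matrix(cells[i, c(1, 3, 2, 4)], 2)
    expect_equal(compute_prr(do.call(contingency_table,
                                     as.list(cells[i, ])))$chi2,
                 unname(chisq.test(m, correct = FALSE)$statistic),
                 tolerance = 1e-9)
  }
})

test_that("ROR and PRR increase strictly in a with b, c, d fixed", {
  b <- 40; c <- 25; d <- 900
  ror <- sapply(1:30, function(a) compute_ror(contingency_table(a, b, c, d))$ror)
  prr <- sapply(1:30, function(a) compute_prr(contingency_table(a, b, c, d))$prr)
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
})

test_that("zero cells are Haldane-corrected, flagged, and never infinite", {
  for (z in 1:4) {
    cells <- c(12, 30, 20, 500)
    cells[z] <- 0
    tab <- do.call(contingency_table, as.list(cells))
    r <- compute_ror(tab); p <- compute_prr(tab); ic <- compute_ic(tab)
    vals <- c(r$ror, r$ci_low, r$ci_high, p$prr, p$chi2, ic$ic)
    expect_true(all(is.finite(vals)))
    expect_true(r$zero_corrected && p$zero_corrected && ic$zero_corrected)
    # correction equals direct evaluation on +0.5 cells
    cc <- cells + 0.5
    expect_equal(r$ror, (cc[1] / cc[2]) / (cc[3] / cc[4]))
  }
  # chi-squared stays on raw counts: degenerate margins report 0
  degen <- contingency_table(0, 0, 10, 90)
  expect_equal(compute_prr(degen)$chi2, 0)
  expect_true(compute_prr(degen)$degenerate)
})

test_that("IC crosses zero exactly at independence (a*N = (a+b)(a+c))", {
  set.seed(7)
  cells <- rand_cells(300, lo = 1, hi = 500)
  for (i in seq_len(nrow(cells))) {
    a <- cells[i, 1]; b <- cells[i, 2]; c <- cells[i, 3]; d <- cells[i, 4]
    ic <- compute_ic(contingency_table(a, b, c, d))$ic
    lhs <- a * (a + b + c + d); rhs <- (a + b) * (a + c)
    if (lhs > rhs) expect_gt(ic, 0)
    if (lhs < rhs) expect_lt(ic, 0)
    if (lhs == rhs) expect_equal(ic, 0)
  }
})

test_that("the CI is symmetric on the log scale around the ROR", {
  set.seed(13)
  cells <- rand_cells(100)
  for (i in seq_len(nrow(cells))) {
    r <- compute_ror(do.call(contingency_table, as.list(cells[i, ])))
    expect_equal(sqrt(r$ci_low * r$ci_high), r$ror, tolerance = 1e-10)
  }
})

test_that("positivity criteria follow the three published rules", {
  # strong signal: all three algorithms fire
  strong <- evaluate_signal(contingency_table(10, 50, 100, 10000))
  expect_true(strong$ror_positive && strong$prr_positive &&
                strong$bcpnn_positive && strong$positive)

  # independence: none fire
  null <- evaluate_signal(contingency_table(10, 90, 90, 810))
  expect_false(null$ror_positive || null$prr_positive ||
                 null$bcpnn_positive || null$positive)

  # N thresholds: a = 1 blocks the ROR rule, a = 2 blocks the PRR rule
  a1 <- evaluate_signal(contingency_table(1, 1, 1, 1000))
  expect_false(a1$ror_positive)
  a2 <- evaluate_signal(contingency_table(2, 1, 1, 1000))
  expect_true(a2$ror_positive)
  expect_false(a2$prr_positive)

  # overall flag is the OR of the three
  set.seed(31)
  cells <- rand_cells(200, lo = 0, hi = 50)
  cells <- cells[rowSums(cells) > 0, , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    s <- evaluate_signal(do.call(contingency_table, as.list(cells[i, ])))
    expect_identical(s$positive,
                     s$ror_positive || s$prr_positive || s$bcpnn_positive)
    expect_true(s$ror_ci["low"] <= s$ror && s$ror <= s$ror_ci["high"])
    expect_gte(s$chi2, 0)
  }
})

test_that("the multiplicative IC025 couples the BCPNN flag to ROR > 1", {
  # IC > 0 iff ad > bc iff ROR > 1, and exp(log(IC) - 1.96 s) > 0 whenever
  # evaluable -- so under the default mode the BCPNN flag fires exactly when
  # IC > 0, i.e. whenever the ROR point estimate exceeds 1
  set.seed(17)
  cells <- rand_cells(200, lo = 1, hi = 200)
  for (i in seq_len(nrow(cells))) {
    tab <- do.call(contingency_table, as.list(cells[i, ]))
    s <- evaluate_signal(tab)
    expect_identical(s$bcpnn_positive, s$ror > 1)
  }

  # under the additive mode a table can be positive via the ROR rule alone;
  # found by brute-force search over small tables
  found <- FALSE
  for (b in 0:5) for (cc in 0:5) for (d in 0:50) {
    tab <- tryCatch(contingency_table(2, b, cc, d), error = function(e) NULL)
    if (is.null(tab)) next
    s <- evaluate_signal(tab, ic_mode = "ic_minus_2sd")
    if (s$ror_positive && !s$prr_positive && !s$bcpnn_positive && s$positive) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("signal tables format to the published two-decimal layout", {
  coll <- mk_collection(c(
    lapply(1:8, function(i) list(id = sprintf("A%d", i),
                                 drugs = c(x = "primary_suspect"),
                                 pts = if (i <= 6) 10043882L else 2L)),
    lapply(1:40, function(i) list(id = sprintf("B%d", i),
                                  drugs = c(y = "primary_suspect"),
                                  pts = if (i <= 4) 10043882L else 2L))))
  smq <- hearing_impairment_smq()
  tab <- signal_table(coll, c("x", "y"), smq)
  expect_equal(nrow(tab), 2)
  disp <- format_signal_table(tab)
  # display strings agree with half-up rounding of the machine values
  expect_match(disp$`PRR (chi2)`[1],
               sprintf("^%.2f", round_half_up(tab$prr[1], 2)))
  masked <- format_signal_table(tab, min_n = 100)
  expect_true(all(masked$`ROR (95% CI)` == "-"))
})
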