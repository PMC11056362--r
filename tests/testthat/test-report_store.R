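test_that("reader joins the four tables, attaches rows by key, and logs drops", {
  paths <- write_fixture_tables(tempfile("fx"))
  expect_warning(
    x <- read_reports(paths["demo"], paths["drug"], paths["reac"],
                      paths["outc"], dialect = "dollar_delimited"),
    "orphan drug row"
  )
  expect_s3_class(x, "report_collection")
  expect_equal(n_reports(x), 3)
  expect_setequal(report_ids(x), c("R1", "R2", "R3"))

  # per-report attachments, hand-joined
  expect_equal(sort(x$drugs$drug_name[x$drugs$report_id == "R1"]),
               c("sildenafil", "warfarin"))
  expect_equal(x$drugs$role[x$drugs$report_id == "R1" &
                              x$drugs$drug_name == "sildenafil"],
               "primary_suspect")
  expect_equal(sort(x$reactions$pt_code[x$reactions$report_id == "R2"]),
               c(10019211L, 10048865L))
  expect_equal(x$reactions$pt_term[x$reactions$report_id == "R3"], "Tinnitus")
  expect_true(is.na(x$reactions$pt_code[x$reactions$report_id == "R3"]))
  expect_setequal(x$outcomes$outcome[x$outcomes$report_id == "R2"],
                  c("disability", "death"))

  # field parsing: unparseable age logged and set unknown; sex normalized
  expect_true(is.na(x$demo$age[x$demo$report_id == "R2"]))
  expect_equal(x$demo$sex, c("male", "female", "unknown"))
  expect_true(any(grepl("unparseable or out-of-range age", load_log(x))))
  # orphan drug row skip is logged, report count unaffected
  expect_true(any(grepl("R9 not in demographics", load_log(x))))
})

test_that("reader is fatal on missing files and absent join keys", {
  paths <- write_fixture_tables(tempfile("fx"))
  expect_error(read_reports(tempfile(), paths["drug"], paths["reac"],
                            paths["outc"]), "not found")
  bad <- file.path(tempfile("bad")); dir.create(bad)
  writeLines(c("id$case_id$age$sex$country$year", "R1$C1$1$m$US$2010"),
             file.path(bad, "demo.txt"))
  expect_error(
    read_reports(file.path(bad, "demo.txt"), paths["drug"], paths["reac"],
                 paths["outc"]),
    "report_id"
  )
})

test_that("an empty reaction table empties the collection", {
  paths <- write_fixture_tables(tempfile("fx"))
  writeLines("report_id$pt_code$pt_term", paths["reac"])
  expect_warning(
    x <- read_reports(paths["demo"], paths["drug"], paths["reac"],
                      paths["outc"]),
    "orphan")
  expect_equal(n_reports(x), 0)
  expect_true(any(grepl("no reaction", load_log(x))))
})

test_that("comma dialect parses quoted fields containing commas", {
  dir <- tempfile("cs"); dir.create(dir)
  writeLines(c("report_id,case_id,age,sex,country,year",
               "R1,C1,60,m,US,2010"), file.path(dir, "demo.txt"))
  writeLines(c("report_id,drug_name,role_code,dose,indication",
               'R1,sildenafil,PS,"20 mg, once",'), file.path(dir, "drug.txt"))
  writeLines(c("report_id,pt_code,pt_term", "R1,10043882,Tinnitus"),
             file.path(dir, "reac.txt"))
  writeLines("report_id,outcome_code", file.path(dir, "outc.txt"))
  x <- read_reports(file.path(dir, "demo.txt"), file.path(dir, "drug.txt"),
                    file.path(dir, "reac.txt"), file.path(dir, "outc.txt"),
                    dialect = "comma_delimited")
  expect_equal(x$drugs$dose_text, "20 mg, once")
})

test_that("deduplication keeps the greatest report_id per case and is idempotent", {
  two <- mk_collection(list(
    list(id = "A1", case = "K", drugs = c(sildenafil = "primary_suspect"),
         pts = 10043882L),
    list(id = "A2", case = "K", drugs = c(sildenafil = "primary_suspect"),
         pts = 10043882L)))
  d <- deduplicate(two)
  expect_equal(report_ids(d), "A2")

  # all-distinct case ids: returned unchanged
  distinct <- mk_collection(lapply(1:4, function(i) {
    list(id = paste0("R", i), drugs = c(x = "primary_suspect"),
         pts = 10043882L)
  }))
  expect_equal(report_ids(deduplicate(distinct)), report_ids(distinct))

  # 10 reports over 7 cases (3 cases duplicated) -> 7 retained
  ten <- mk_collection(lapply(1:10, function(i) {
    list(id = sprintf("R%02d", i),
         case = sprintf("C%d", c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7)[i]),
         drugs = c(x = "primary_suspect"), pts = 10043882L)
  }))
  d10 <- deduplicate(ten)
  expect_equal(n_reports(d10), 7)
  # idempotence and case-id preservation
  expect_identical(deduplicate(d10)$demo, d10$demo)
  expect_setequal(unique(d10$demo$case_id), unique(ten$demo$case_id))
})

test_that("primary-suspect filtering is role- and report-level", {
  coll <- mk_collection(list(
    list(id = "R1", drugs = c(x = "primary_suspect"), pts = 1L),
    list(id = "R2", drugs = c(x = "concomitant", y = "primary_suspect"),
         pts = 1L),
    list(id = "R3", drugs = c(x = "primary_suspect", y = "concomitant"),
         pts = 1L),
    list(id = "R4", drugs = c(y = "primary_suspect"), pts = 1L),
    list(id = "R5", drugs = c(x = "secondary_suspect"), pts = 1L),
    list(id = "R6", drugs = c(z = "primary_suspect"), pts = 1L)))
  f <- filter_primary_suspect(coll, "x")
  expect_setequal(report_ids(f), c("R1", "R3"))   # 2 of 6 retained
  expect_equal(n_reports(filter_primary_suspect(coll, "absent")), 0)

  # two entries for the drug, one primary suspect -> included once
  dup_entry <- mk_collection(list(
    list(id = "R1", drugs = c(x = "primary_suspect", x = "concomitant"),
         pts = 1L)))
  expect_equal(report_ids(filter_primary_suspect(dup_entry, "X ")), "R1")
})

test_that("collections round-trip through the writer and reader", {
  cfg <- synth_config(n_reports = 150, p_duplicate = 0.2)
  x <- generate_reports(cfg, seed = 11)
  for (dialect in c("dollar_delimited", "comma_delimited")) {
    paths <- write_reports(x, tempfile("rt"), dialect)
    y <- read_reports(paths["demo"], paths["drug"], paths["reac"],
                      paths["outc"], dialect)
    for (tb in c("demo", "drugs", "reactions", "outcomes")) {
      expect_equal(y[[tb]], x[[tb]], ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("collection invariants are enforced", {
  base <- list(id = "R1", drugs = c(x = "primary_suspect"), pts = 1L)
  expect_error(mk_collection(list(base, base)), "duplicate report_id")
  bad_age <- modifyList(base, list(age = 150))
  expect_error(mk_collection(list(bad_age)), "age outside")
  # a report needs >= 1 drug and >= 1 reaction
  coll <- mk_collection(list(base))
  expect_error(report_collection(coll$demo, coll$drugs,
                                 coll$reactions[0, ]), "without any reaction")
  expect_error(report_collection(coll$demo, coll$drugs[0, ],
                                 coll$reactions), "without any drug")
})
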