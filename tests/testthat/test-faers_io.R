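test_that("quarter parsing preserves rows, normalizes dialects, and accounts for malformed lines", {
  dir <- withr::local_tempdir()
  paths <- write_quarter_fixture(dir, list(
    DEMO = c("PRIMARYID$CASEID$FDA_DT$EVENT_DT$SEX",
             "101$11$20230101$20230105$F",
             "102$12$20230201$20230210$M",
             "103$13$20230301$$"),
    DRUG = c("PRIMARY_ID$DRUG_SEQ$DRUGNAME$ROLE_COD",  # legacy underscore dialect
             "101$1$ABECMA$PS",
             "102$1$OTHERDRUG$C"),
    REAC = c("PRIMARYID$PT",
             "101$Pyrexia",
             "101$Cytokine release syndrome",
             "102$Pyrexia")
  ))
  raw <- parse_quarter(paths, "2023Q1")
  expect_s3_class(raw, "faers_raw")
  expect_equal(nrow(raw$tables$DEMO), 3L)
  expect_equal(names(raw$tables$DRUG)[1], "PRIMARYID")
  expect_equal(raw$tables$DEMO$PRIMARYID, c("101", "102", "103"))
  expect_identical(raw$log$DEMO$n_malformed, 0L)
})

test_that("a trailing '$' yields an empty final field with a logged warning, not a dropped row", {
  dir <- withr::local_tempdir()
  paths <- write_quarter_fixture(dir, list(
    DEMO = c("PRIMARYID$CASEID$FDA_DT",
             "101$11$20230101$",   # extra trailing delimiter
             "102$12$20230201"),
    DRUG = c("PRIMARYID$DRUGNAME$ROLE_COD", "101$X$PS"),
    REAC = c("PRIMARYID$PT", "101$Nausea")
  ))
  expect_warning(raw <- parse_quarter(paths), "trailing")
  expect_equal(nrow(raw$tables$DEMO), 2L)
  # manual split of the fixture line: the data fields are exactly 101/11/20230101
  expect_equal(unlist(raw$tables$DEMO[1, ], use.names = FALSE),
               c("101", "11", "20230101"))
  expect_equal(raw$log$DEMO$n_trailing_extra, 1L)
})

test_that("short and long rows are coerced and counted, and missing mandatory tables are fatal", {
  dir <- withr::local_tempdir()
  paths <- write_quarter_fixture(dir, list(
    DEMO = c("PRIMARYID$CASEID$FDA_DT",
             "101$11",                      # short row -> padded
             "102$12$20230101$EXTRA$MORE"), # long row -> truncated
    DRUG = c("PRIMARYID$DRUGNAME$ROLE_COD", "101$X$PS"),
    REAC = c("PRIMARYID$PT", "101$Nausea")
  ))
  expect_warning(raw <- parse_quarter(paths), "malformed")
  expect_equal(nrow(raw$tables$DEMO), 2L)
  expect_equal(raw$log$DEMO$n_malformed, 2L)
  expect_true(is.na(raw$tables$DEMO$FDA_DT[1]))

  expect_error(parse_quarter(paths["DEMO"]), "mandatory")
  expect_error(parse_quarter(c(paths, OUTC = file.path(dir, "nope.txt"))), "not found")
})

test_that("partial dates impute to interval midpoints and carry the imprecision flag", {
  p <- parse_faers_date(c("20230620", "202306", "2023", "", "20231345", "bad1x"))
  expect_equal(p$date[1:3], as.Date(c("2023-06-20", "2023-06-15", "2023-07-01")))
  expect_equal(p$imprecise[1:3], c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(p$date[4:6])))
  expect_true(all(is.na(p$imprecise[4:6])))
})

test_that("assembly joins satellites on PRIMARYID, types fields, and excludes orphans", {
  dir <- withr::local_tempdir()
  paths <- write_quarter_fixture(dir, list(
    DEMO = c("PRIMARYID$CASEID$FDA_DT$EVENT_DT$AGE$AGE_COD$SEX$WT$WT_COD$OCCP_COD$OCCR_COUNTRY",
             "101$11$20230101$202306$72$YR$F$154$LBS$MD$US"),
    DRUG = c("PRIMARYID$DRUG_SEQ$DRUGNAME$ROLE_COD",
             "101$1$ABECMA$PS",
             "101$2$LENALIDOMIDE$C",
             "999$1$GHOST$PS"),       # orphan
    REAC = c("PRIMARYID$PT",
             "101$Pyrexia", "101$Nausea", "101$Tremor",
             "999$Ghost event"),      # orphan
    THER = c("PRIMARYID$DSG_DRUG_SEQ$START_DT",
             "101$1$20230510")
  ))
  suppressMessages(rep <- assemble_reports(parse_quarter(paths)))
  expect_equal(nreports(rep), 1L)
  expect_equal(nrow(rep$drugs), 2L)
  expect_equal(nrow(rep$reactions), 3L)
  expect_equal(sum(attr(rep, "orphans")), 2L)
  d <- rep$demo
  expect_equal(d$age_years, 72)
  expect_equal(d$weight_kg, 154 * 0.45359237)
  expect_equal(d$reporter, "healthcare_professional")
  # EVENT_DT "202306" -> midpoint rule
  expect_equal(d$event_dt, as.Date("2023-06-15"))
  expect_true(d$event_imprecise)
  expect_equal(rep$drugs$start_dt[rep$drugs$drug_seq == "1"], as.Date("2023-05-10"))
})

test_that("a quarter without THER assembles with unknown therapy starts throughout", {
  dir <- withr::local_tempdir()
  paths <- write_quarter_fixture(dir, list(
    DEMO = c("PRIMARYID$CASEID$FDA_DT$EVENT_DT", "101$11$20230101$20230105"),
    DRUG = c("PRIMARYID$DRUGNAME$ROLE_COD", "101$ABECMA$PS"),
    REAC = c("PRIMARYID$PT", "101$Pyrexia")
  ))
  rep <- assemble_reports(parse_quarter(paths))
  expect_true(all(is.na(rep$drugs$start_dt)))
  tt <- compute_tto(rep, drug_query("ide-cel", "abecma"))
  expect_true(all(tt$validity == "missing_start"))
})

test_that("deduplication keeps latest FDA_DT, breaks ties by higher PRIMARYID, unknown date loses", {
  rep <- mk_reports(demo = data.frame(
    primaryid = c("100", "101", "99", "300", "301", "400", "401", "500"),
    caseid    = c("A",   "A",   "A",  "B",   "B",   "C",   "C",   "D"),
    fda_dt    = as.Date(c("2023-01-01", "2023-03-01", "2023-03-01",
                          "2023-05-01", NA,
                          "2023-02-01", "2023-02-01", "2023-09-09"))
  ))
  dd <- deduplicate(rep)
  # case A: 101 and 99 tie on the latest date; numeric comparison keeps 101
  # case B: dated 300 beats undated 301; case C: tie -> higher id 401
  expect_setequal(dd$demo$primaryid, c("101", "300", "401", "500"))
  expect_equal(attr(dd, "removed"), 4L)
})

test_that("deduplication is idempotent, conservative, and order-invariant", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    rep <- mk_reports(demo = data.frame(
      primaryid = as.character(sample(1000:9999, n)),
      caseid = as.character(sample(1:25, n, replace = TRUE)),
      fda_dt = as.Date("2020-01-01") + sample(0:1000, n, replace = TRUE)
    ))
    dd <- deduplicate(rep)
    expect_equal(nreports(dd) + attr(dd, "removed"), n)
    expect_equal(anyDuplicated(dd$demo$caseid), 0L)
    dd2 <- deduplicate(dd)
    expect_equal(dd2$demo, dd$demo)
    expect_equal(attr(dd2, "removed"), 0L)
    perm <- sample(n)
    rep_p <- mk_reports(demo = as.data.frame(rep$demo)[perm, ])
    expect_equal(deduplicate(rep_p)$demo, dd$demo)
  }
})

test_that("a deduplicated set round-trips through the TSV output format", {
  cfg <- simulation_config(n_reports = 150, n_background_pts = 30, seed = 11)
  dd <- deduplicate(sim_reports(simulate_faers(cfg)))
  dir <- withr::local_tempdir()
  write_reports(dd, dir)
  back <- read_reports(dir)
  for (tab in c("demo", "drugs", "reactions", "outcomes"))
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(dd[[tab]]))
  expect_equal(attr(back, "removed"), attr(dd, "removed"))
})
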