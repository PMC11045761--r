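test_that("quarter files parse with verbatim values and explicit missing", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$event_dt$fda_dt$age$age_cod$sex$occp_cod$reporter_country",
               "101$20210103$20210201$65$YR$F$MD$US",
               "102$$20210202$$$M$PH$JP",
               "103$202102$20210203$6.5$DEC$$CN$"),
             file.path(dir, "DEMO21Q1.txt"))
  for (tb in c("DRUG", "REAC", "OUTC", "THER")) {
    hdr <- switch(tb,
                  DRUG = "primaryid$drug_seq$role_cod$drugname",
                  REAC = "primaryid$pt",
                  OUTC = "primaryid$outc_cod",
                  THER = "primaryid$dsg_drug_seq$start_dt$end_dt")
    writeLines(hdr, file.path(dir, paste0(tb, "21Q1.txt")))
  }
  rq <- read_quarter(dir, "2021Q1")
  expect_equal(nrow(rq$demo), 3)
  expect_equal(nrow(rq$reac), 0)
  expect_equal(rq$demo$age, c("65", NA, "6.5"))
  expect_true(is.na(rq$demo$event_dt[2]))         # trailing/empty -> NA
  expect_identical(rq$demo$reporter_country[1:2], c("US", "JP"))
})

test_that("absent files and malformed input are hard errors naming the spot", {
  dir <- withr::local_tempdir()
  expect_error(read_quarter(dir, "2021Q1"), "DEMO")
  writeLines(c("primaryid$pt", "1$Rash$extra$fields$way$too$many"),
             file.path(dir, "X.txt"))
  expect_error(faersignal:::read_faers_table(file.path(dir, "X.txt"), "reac"),
               "line 2")
  writeLines(character(0), file.path(dir, "Y.txt"))
  expect_error(faersignal:::read_faers_table(file.path(dir, "Y.txt"), "demo"),
               "header")
  expect_error(read_quarter(dir, "21Q1"), "YYYYQn")
})

test_that("write -> read round-trips a quarter exactly", {
  sim <- generate_reports(sim_config(n_background = 150, n_target = 50,
                                     duplicate_rate = 0.1, seed = 42))
  dir <- withr::local_tempdir()
  write_quarter(sim$quarter, dir)
  back <- read_quarter(dir, sim$quarter$quarter_label)
  for (tb in c("demo", "drug", "reac", "outc", "ther")) {
    a <- sim$quarter[[tb]]
    a[!is.na(a) & a == ""] <- NA            # writer maps "" and NA alike
    expect_equal(back[[tb]], a, ignore_attr = TRUE)
  }
  # second write of the re-read quarter is byte-identical
  dir2 <- withr::local_tempdir()
  write_quarter(back, dir2)
  for (f in list.files(dir)) {
    expect_identical(readBin(file.path(dir, f), "raw", file.size(file.path(dir, f))),
                     readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))))
  }
})

test_that("values with embedded spaces survive writing unmangled", {
  rq <- toy_quarter(list(list(id = "1", pts = "Deep vein thrombosis",
                              drugs = "RYBREVANT 350 MG")))
  dir <- withr::local_tempdir()
  write_quarter(rq, dir)
  back <- read_quarter(dir, "2021Q1")
  expect_identical(back$reac$pt, "Deep vein thrombosis")
  expect_identical(back$drug$drugname, "RYBREVANT 350 MG")
})

test_that("assembly joins children, drops orphans and empty reports", {
  rq <- toy_quarter(list(
    list(id = "1", drugs = c("AMIVANTAMAB", "CARBOPLATIN"),
         pts = c("Rash", "Nausea", "Hypotension"), outc = c("HO", "DE")),
    list(id = "2", pts = "Pyrexia")
  ))
  # orphan REAC row + a DEMO report with no reactions
  rq$reac <- rbind(rq$reac, data.frame(primaryid = "99", pt = "Cough"))
  rq$demo <- rbind(rq$demo, rq$demo[2, ])
  rq$demo$primaryid[3] <- "3"
  expect_warning(cases <- assemble_cases(rq), "REAC")
  expect_equal(n_cases(cases), 2)
  expect_equal(sum(cases$drugs$case_id == "1"), 2)
  expect_equal(sum(cases$reactions$case_id == "1"), 3)
  expect_equal(sort(cases$outcomes$outcome[cases$outcomes$case_id == "1"]),
               c("DE", "HO"))
  log <- cases$log[[1]]
  expect_equal(log$orphan_reac_rows, 1L)
  expect_equal(log$no_reaction_reports, 1L)
})

test_that("assembly is insensitive to input row order", {
  sim <- generate_reports(sim_config(n_background = 120, n_target = 40,
                                     duplicate_rate = 0, seed = 7))
  rq <- sim$quarter
  shuffled <- rq
  set.seed(99)
  for (tb in c("demo", "drug", "reac", "outc", "ther")) {
    shuffled[[tb]] <- shuffled[[tb]][sample(nrow(shuffled[[tb]])), , drop = FALSE]
    rownames(shuffled[[tb]]) <- NULL
  }
  a <- assemble_cases(rq)
  b <- assemble_cases(shuffled)
  for (tb in c("demo", "drugs", "outcomes")) {
    expect_equal(b[[tb]], a[[tb]], ignore_attr = TRUE)
  }
  # reactions may repeat a PT within a case; compare as sorted multisets
  expect_equal(b$reactions[order(b$reactions$case_id, b$reactions$pt), ],
               a$reactions[order(a$reactions$case_id, a$reactions$pt), ],
               ignore_attr = TRUE)
})

test_that("age normalization follows the unit semantics", {
  expect_equal(normalize_age(65, "YR"), 65)
  expect_equal(normalize_age(780, "MON"), 65)
  expect_equal(normalize_age(6.5, "DEC"), 65)
  expect_equal(normalize_age(14, "WK"), 14 * 7 / 365.25)
  expect_true(is.na(normalize_age(-5, "YR")))
  expect_true(is.na(normalize_age(65, "??")))
  expect_true(is.na(normalize_age(200, "YR")))    # out of [0, 130]
  # monotone in value for a fixed unit; agrees with direct arithmetic
  for (unit in c("YR", "DEC", "MON", "WK", "DY", "HR")) {
    v <- sort(runif(20, 0, 100))
    got <- normalize_age(v, unit)
    fac <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
             DY = 1 / 365.25, HR = 1 / 8766)[[unit]]
    ref <- v * fac
    ref[ref > 130] <- NA
    expect_equal(got, ref, tolerance = 1e-9)
    expect_false(is.unsorted(got[!is.na(got)]))
  }
})

test_that("country-to-region lookup is total and deterministic", {
  expect_equal(map_country_to_region(c("US", "JP", "FR", "BR", "AU", "ZA")),
               c("NorthAmerica", "Asia", "Europe", "SouthAmerica",
                 "Oceania", "Africa"))
  expect_equal(map_country_to_region(c("", "XX", NA)), rep("UNK", 3))
  expect_equal(map_country_to_region("ru"), "Europe")  # case-insensitive, M49
  expect_equal(map_country_to_region("TR"), "Asia")
})
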