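target_names <- c("AMIVANTAMAB", "RYBREVANT")

# 6 toy cases: 2 target+event, 1 target only, 1 event only, 2 neither.
six_case_cohort <- function(extra_pt_for_first = FALSE) {
  pts1 <- if (extra_pt_for_first) c("Pulmonary embolism", "Deep vein thrombosis")
          else "Pulmonary embolism"
  toy_cases(list(
    list(id = "1", drugs = "AMIVANTAMAB", pts = pts1),
    list(id = "2", drugs = "AMIVANTAMAB", pts = "Pulmonary embolism"),
    list(id = "3", drugs = "AMIVANTAMAB", pts = "Rash"),
    list(id = "4", drugs = "OSIMERTINIB", pts = "Pulmonary embolism"),
    list(id = "5", drugs = "OSIMERTINIB", pts = "Rash"),
    list(id = "6", drugs = "CARBOPLATIN", pts = "Nausea")
  ))
}

test_that("contingency counts match the case/non-case layout", {
  lab <- label_cases(six_case_cohort(), drug_names = target_names)
  tab <- build_contingency(lab, "venous_thrombotic_diseases", "report")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 2, b = 1, c = 1, d = 2))
  # in event-pair mode an extra mapped PT on one target case lifts a to 3
  lab2 <- label_cases(six_case_cohort(extra_pt_for_first = TRUE),
                      drug_names = target_names)
  tab2 <- build_contingency(lab2, "venous_thrombotic_diseases", "event_pair")
  expect_equal(tab2$a, 3)
  # degenerate: every case is target + event
  lab3 <- label_cases(toy_cases(list(
    list(id = "1", drugs = "AMIVANTAMAB", pts = "Pulmonary embolism"),
    list(id = "2", drugs = "AMIVANTAMAB", pts = "Embolism"))),
    drug_names = target_names)
  tab3 <- build_contingency(lab3, "venous_thrombotic_diseases", "report")
  expect_equal(unlist(tab3[c("a", "b", "c", "d")]), c(a = 2, b = 0, c = 0, d = 0))
  # no target-drug cases at all is a hard error
  lab4 <- label_cases(toy_cases(list(list(id = "1", drugs = "OSIMERTINIB"))),
                      drug_names = target_names)
  expect_error(build_contingency(lab4, "arrhythmia", "report"), "target")
})

test_that("contingency equals exhaustive double-loop counting", {
  mapping <- load_smq_mapping()
  pool <- c(mapping$pt, "Rash", "Nausea", "Cough")
  drugs_pool <- c("AMIVANTAMAB", "OSIMERTINIB", "CARBOPLATIN")
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    specs <- lapply(seq_len(n), function(i)
      list(id = sprintf("%03d", i),
           drugs = sample(drugs_pool, sample(1:2, 1)),
           pts = sample(pool, sample(1:3, 1))))
    lab <- label_cases(toy_cases(specs), drug_names = target_names)
    if (!any(lab$labels$is_target)) next
    for (ev in sample(smq_ids(mapping), 3)) {
      smq_pts <- tolower(mapping$pt[mapping$smq_id == ev])
      # brute force over cases
      a <- b <- cc <- d <- 0
      for (cs in specs) {
        target <- any(cs$drugs == "AMIVANTAMAB")
        event <- any(tolower(cs$pts) %in% smq_pts)
        if (target && event) a <- a + 1
        else if (target) b <- b + 1
        else if (event) cc <- cc + 1
        else d <- d + 1
      }
      tab <- build_contingency(lab, ev, "report")
      expect_equal(unlist(tab[c("a", "b", "c", "d")]),
                   c(a = a, b = b, c = cc, d = d))
      # brute force over (case, PT) pairs
      a2 <- b2 <- c2 <- d2 <- 0
      for (cs in specs) {
        target <- any(cs$drugs == "AMIVANTAMAB")
        for (pt in unique(tolower(cs$pts))) {
          event <- pt %in% smq_pts
          if (target && event) a2 <- a2 + 1
          else if (target) b2 <- b2 + 1
          else if (event) c2 <- c2 + 1
          else d2 <- d2 + 1
        }
      }
      tab2 <- build_contingency(lab, ev, "event_pair")
      expect_equal(unlist(tab2[c("a", "b", "c", "d")]),
                   c(a = a2, b = b2, c = c2, d = d2))
    }
  }
})

test_that("ROR point estimate and Wald interval match closed forms", {
  expect_equal(ror_with_ci(contingency_table(10, 10, 10, 10))$ror, 1.0)
  expect_equal(ror_with_ci(contingency_table(5, 5, 5, 85))$ror, 17.0)
  r <- ror_with_ci(contingency_table(10, 10, 10, 10))
  expect_equal(r$ror025, exp(-qnorm(0.975) * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(r$ror975, exp(qnorm(0.975) * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(round(r$ror025, 2), 0.29)
  expect_equal(round(r$ror975, 2), 3.45)
  # zero cell: undefined with a reason, not an exception
  z <- ror_with_ci(contingency_table(0, 10, 10, 10))
  expect_true(is.na(z$ror) && z$reason == "zero_cell")
  zc <- ror_with_ci(contingency_table(0, 10, 10, 10), continuity = TRUE)
  expect_equal(zc$ror, 0.5 * 10.5 / (10.5 * 10.5))
})

test_that("ROR symmetry properties hold", {
  set.seed(17)
  for (i in 1:50) {
    abcd <- sample(1:200, 4, replace = TRUE)
    r1 <- ror_with_ci(do.call(contingency_table, as.list(abcd)))$ror
    r_swap <- ror_with_ci(contingency_table(abcd[4], abcd[3], abcd[2], abcd[1]))$ror
    r_flip <- ror_with_ci(contingency_table(abcd[2], abcd[1], abcd[4], abcd[3]))$ror
    expect_equal(r1, r_swap, tolerance = 1e-12)
    expect_equal(r1 * r_flip, 1, tolerance = 1e-12)
  }
})

test_that("shrinkage IC matches its closed form and limits", {
  r <- ic_with_ci(contingency_table(10, 10, 10, 10))
  expect_equal(r$expected, 10)
  expect_equal(r$ic, 0)
  r2 <- ic_with_ci(contingency_table(40, 60, 160, 740))
  expect_equal(r2$expected, 20)
  expect_equal(r2$ic, log2(40.5 / 20.5), tolerance = 1e-12)
  # a = 0 stays defined and negative under shrinkage
  expect_lt(ic_with_ci(contingency_table(0, 100, 100, 9800))$ic, 0)
  # shrinkage vanishes as a grows with fixed a/E, and never inflates |ic|
  for (scale in c(1, 10, 100, 1000)) {
    tab <- contingency_table(20 * scale, 80 * scale, 100 * scale, 9800 * scale)
    ic <- ic_with_ci(tab)
    raw <- log2(tab$a / ic$expected)
    expect_lte(abs(ic$ic), abs(raw) + 1e-12)
    if (scale == 1000) expect_equal(ic$ic, raw, tolerance = 1e-3)
  }
  # Noren credible approximation is asymmetric around the point estimate
  nc <- ic_with_ci(contingency_table(40, 60, 160, 740), "noren_credible")
  expect_lt(nc$ic975 - nc$ic, nc$ic - nc$ic025)
  expect_true(nc$ic025 <= nc$ic && nc$ic <= nc$ic975)
})

test_that("signal flag combines the interval criterion with the count gate", {
  expect_true(flag_signal(list(a = 47, ror025 = 9.23, ic025 = NA)))
  expect_true(flag_signal(list(a = 21, ror025 = 1.16, ic025 = NA)))
  expect_false(flag_signal(list(a = 2, ror025 = 5.0, ic025 = 3)))
  expect_false(flag_signal(list(a = 10, ror025 = 0.8, ic025 = -0.2)))
  expect_true(flag_signal(list(a = 10, ror025 = NA, ic025 = 0.3)))
})

test_that("the screen recovers an enriched SMQ and is deterministic", {
  cfg <- sim_config(n_background = 4000, n_target = 800,
                    duplicate_rate = 0, seed = 21)
  sim <- generate_reports(cfg)
  lab <- label_cases(assemble_cases(sim$quarter),
                     drug_names = "AMIVANTAMAB")
  scr <- run_screen(lab, counting_unit = "report")
  expect_s3_class(scr, "signal_screen")
  expect_true(scr$signal[scr$event_id == "venous_thrombotic_diseases"])
  # unenriched rare SMQs must not dominate: sorted by a descending
  expect_true(all(diff(scr$a) <= 0))
  scr2 <- run_screen(lab, counting_unit = "report")
  expect_identical(scr, scr2)
  # PT-level screening rides alongside SMQs
  scr3 <- run_screen(lab, pt_list = "Pulmonary embolism",
                     counting_unit = "report")
  expect_true("Pulmonary embolism" %in% scr3$event_id)
})
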