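test_that("outcome summaries give exact proportions on the fixture", {
  fx <- table1_fixture()
  cardio_ids <- fx$labels$case_id[fx$labels$is_cardio]
  mace_ids <- fx$labels$case_id[fx$labels$is_mace]
  s_cardio <- outcome_summary(fx, cardio_ids, "cardio")
  expect_equal(s_cardio$n, 98)
  expect_equal(s_cardio$p_death, 16 / 98)
  expect_equal(s_cardio$p_hospitalization, 60 / 98)
  expect_equal(s_cardio$p_life_threatening, 16 / 98)
  s_mace <- outcome_summary(fx, mace_ids, "mace")
  expect_equal(s_mace$p_death, 6 / 10)
  # empty group and flag-free case
  s_none <- outcome_summary(fx, character(0), "none")
  expect_equal(s_none$n, 0)
  expect_true(is.na(s_none$p_death))
})

test_that("baseline table reproduces cohort margins and conserves counts", {
  fx <- table1_fixture()
  bt <- baseline_table(fx)
  cell <- function(var, lv, col) bt[bt$variable == var & bt$level == lv, col]
  expect_equal(cell("sex", "Female", "n_cardio"), 58)
  expect_equal(cell("sex", "Female", "n_non_cardio"), 206)
  expect_equal(cell("reporter", "Doctor", "n_cardio"), 70)
  expect_equal(cell("region", "Asia", "n_cardio"), 41)
  expect_equal(cell("report_year", "2023", "n_non_mace"), 46)
  expect_equal(cell("age_band", ">=75", "n_mace"), 2)
  expect_equal(cell("death", "Unknown", "n_cardio"), 13)
  cn <- attr(bt, "cohort_n")
  expect_equal(unname(cn["non_cardio"] + cn["cardio"]), 595L)
  expect_equal(unname(cn["non_mace"] + cn["mace"]), unname(cn["cardio"]))
  # every variable's levels partition each cohort
  for (v in unique(bt$variable)) {
    expect_equal(sum(bt$n_cardio[bt$variable == v]), 98)
    expect_equal(sum(bt$n_non_cardio[bt$variable == v]), 497)
  }
})

test_that("age bands use [lower, upper) with the top band closed at 130", {
  cases <- toy_cases(list(
    list(id = "1", age = "44", pts = "Rash"),
    list(id = "2", age = "45", pts = "Rash"),
    list(id = "3", age = "75", pts = "Rash"),
    list(id = "4", age = "17", pts = "Rash")
  ))
  lab <- label_cases(cases)
  bt <- baseline_table(lab)
  bands <- bt[bt$variable == "age_band", c("level", "n_non_cardio")]
  got <- setNames(bands$n_non_cardio, bands$level)
  expect_equal(unname(got["18-45"]), 1)
  expect_equal(unname(got["45-65"]), 1)
  expect_equal(unname(got[">=75"]), 1)
  expect_equal(unname(got["<18"]), 1)
})

test_that("chi-squared comparison is Pearson without continuity correction", {
  r0 <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)
  r <- chi_square(matrix(c(20, 5, 5, 20), 2, byrow = TRUE))
  expect_equal(r$chi2, 18.0)
  expect_equal(r$df, 1)
  # independent hand-formula oracle on random tables
  set.seed(41)
  for (i in 1:25) {
    m <- matrix(sample(5:80, 6, replace = TRUE), nrow = 2)
    r <- chi_square(m)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(r$chi2, sum((m - E)^2 / E), tolerance = 1e-8)
    expect_equal(r$df, (nrow(m) - 1) * (ncol(m) - 1))
    expect_equal(r$p_value, pchisq(r$chi2, r$df, lower.tail = FALSE),
                 tolerance = 1e-12)
    # invariance under row/column permutation
    rp <- chi_square(m[2:1, c(2, 3, 1)])
    expect_equal(rp$chi2, r$chi2, tolerance = 1e-10)
  }
})

test_that("unknown levels are excluded from tests but kept in tables", {
  m <- matrix(c(30, 20, 50, 20, 30, 50), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("Yes", "No", "Unknown")))
  r_ex <- chi_square(m, unknown_policy = "exclude")
  expect_equal(ncol(r_ex$counts), 2)
  r_in <- chi_square(m, unknown_policy = "include_as_level")
  expect_equal(ncol(r_in$counts), 3)
  expect_equal(r_in$df, 2)
  expect_equal(r_ex$df, 1)
  # zero-margin level dropped with a warning; degenerate table errors
  m2 <- cbind(m[, 1:2], None = c(0, 0))
  expect_warning(chi_square(m2), "zero-margin")
  expect_error(suppressWarnings(chi_square(cbind(m[, 1, drop = FALSE],
                                                 None = c(0, 0)))),
               "at least")
})
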