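target_names <- c("AMIVANTAMAB", "RYBREVANT")

test_that("target-drug matching uses normalized whole-word containment", {
  cases <- toy_cases(list(
    list(id = "1", drugs = "AMIVANTAMAB"),
    list(id = "2", drugs = "Rybrevant 350MG"),
    list(id = "3", drugs = "OSIMERTINIB"),
    list(id = "4", drugs = c("carboplatin", "amivantamab-vmjw"))
  ))
  m <- match_target_drug(cases, target_names)
  expect_equal(unname(m), c(TRUE, TRUE, FALSE, TRUE))
  # role restriction
  cases2 <- toy_cases(list(list(id = "1", drugs = "AMIVANTAMAB", roles = "C")))
  expect_false(unname(match_target_drug(cases2, target_names,
                                        roles = c("PS", "SS"))))
})

test_that("deduplication collapses reports agreeing on the 7-component key", {
  base <- list(sex = "F", age = "65", country = "US",
               pts = c("Rash", "Hypotension"), drugs = "AMIVANTAMAB",
               start = "20210101", end = "20210301")
  mk <- function(id, ...) c(list(id = id), utils::modifyList(base, list(...)))
  cases <- toy_cases(list(mk("1"), mk("2")))
  dd <- deduplicate(cases)
  expect_equal(n_cases(dd$cases), 1)
  expect_equal(dd$removed_count, 1)
  # representative is the lexicographically greatest case id
  expect_equal(dd$cases$demo$case_id, "2")
  # empty input
  empty <- subset_cases(cases, character(0))
  expect_equal(deduplicate(empty)$removed_count, 0)
})

test_that("near-duplicates differing in any key component are all kept", {
  base <- list(sex = "F", age = "65", country = "US",
               pts = c("Rash", "Hypotension"), drugs = "AMIVANTAMAB",
               start = "20210101", end = "20210301")
  mk <- function(id, ...) c(list(id = id), utils::modifyList(base, list(...)))
  variants <- list(
    mk("v1", sex = "M"), mk("v2", age = "66"), mk("v3", country = "JP"),
    mk("v4", pts = c("Rash", "Hypertension")),
    mk("v5", drugs = c("AMIVANTAMAB", "CARBOPLATIN")),
    mk("v6", start = "20210102"), mk("v7", end = "20210302"),
    mk("v8")                                     # the only true duplicate of v0
  )
  cases <- toy_cases(c(list(mk("v0")), variants))
  dd <- deduplicate(cases)
  expect_equal(dd$removed_count, 1)
  expect_false("v0" %in% dd$cases$demo$case_id)  # v8 kept as representative
})

test_that("deduplication matches a brute-force key oracle and is idempotent", {
  sim <- generate_reports(sim_config(n_background = 80, n_target = 40,
                                     duplicate_rate = 0.15, seed = 11))
  cases <- assemble_cases(sim$quarter)
  oracle_keys <- brute_force_dedup_keys(cases)
  dd <- deduplicate(cases)
  expect_equal(n_cases(dd$cases), length(unique(oracle_keys)))
  expect_equal(dd$removed_count + n_cases(dd$cases), n_cases(cases))
  dd2 <- deduplicate(dd$cases)
  expect_equal(dd2$removed_count, 0)
})

test_that("missing key fields collide as an explicit missing token", {
  cases <- toy_cases(list(
    list(id = "1", sex = "F", pts = "Rash", drugs = "AMIVANTAMAB"),
    list(id = "2", sex = "F", pts = "Rash", drugs = "AMIVANTAMAB")
  ))
  expect_true(all(is.na(cases$demo$age_years)))
  expect_equal(deduplicate(cases)$removed_count, 1)
})

test_that("the shipped SMQ mapping declares 11 groupings and validates", {
  mapping <- load_smq_mapping()
  expect_length(smq_ids(mapping), 11)
  expect_true(all(c("venous_thrombotic_diseases", "abnormal_blood_pressure",
                    "arrhythmia", "pericardial_effusion", "cardiac_failure",
                    "stroke", "sudden_death", "coronary_artery_disease",
                    "myocardial_injury", "peripheral_vascular_disease",
                    "cardiomyopathy_other") %in% smq_ids(mapping)))

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("smq_id\tsmq_name\tpt_term", "one\tOne\tHypotension"), f)
  single <- load_smq_mapping(f)
  expect_length(smq_ids(single), 1)

  writeLines(c("smq_id\tsmq_name\tpt_term",
               "one\tOne\tHypotension", "one\tOther name\tHypertension"), f)
  expect_error(load_smq_mapping(f), "duplicate smq_id")

  writeLines(c("smq_id\tsmq_name\tpt_term", "one\tOne\t"), f)
  expect_error(load_smq_mapping(f), "empty PT set")
})

test_that("classification assigns memberships, MACE and outcome flags", {
  cases <- toy_cases(list(
    list(id = "1", pts = "Pulmonary embolism"),
    list(id = "2", pts = "Rash"),
    list(id = "3", pts = c("Cardiac arrest", "PULMONARY EMBOLISM"),
         outc = c("DE", "HO"))
  ))
  lab <- label_cases(cases, drug_names = target_names)
  l <- lab$labels
  expect_equal(l$is_cardio, c(TRUE, FALSE, TRUE))
  expect_equal(lab$memberships$smq_id[lab$memberships$case_id == "1"],
               "venous_thrombotic_diseases")
  # case-insensitive PT match, MACE via sudden_death
  expect_setequal(lab$memberships$smq_id[lab$memberships$case_id == "3"],
                  c("sudden_death", "venous_thrombotic_diseases"))
  expect_equal(l$is_mace, c(FALSE, FALSE, TRUE))
  expect_true(l$death[3] && l$hospitalization[3] && l$is_serious[3])
  expect_false(l$is_serious[1])
  expect_error(label_cases(cases, mace_smqs = "not_declared"), "not declared")
})

test_that("memberships equal brute-force PT-set intersection on random cases", {
  mapping <- load_smq_mapping()
  all_pts <- c(mapping$pt, "Rash", "Nausea", "Cough", "Pyrexia")
  set.seed(5)
  specs <- lapply(1:30, function(i) {
    list(id = sprintf("%02d", i),
         pts = sample(all_pts, sample(1:4, 1)))
  })
  cases <- toy_cases(specs)
  lab <- label_cases(cases)
  for (i in seq_along(specs)) {
    pts <- tolower(specs[[i]]$pts)
    expected <- unique(mapping$smq_id[mapping$pt_folded %in% pts])
    got <- lab$memberships$smq_id[lab$memberships$case_id == specs[[i]]$id]
    expect_setequal(got, expected)
  }
})
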