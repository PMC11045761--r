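# An in-package fixture of 595 synthetic case records whose marginal counts
# per cohort reproduce a published baseline-characteristics table cell by
# cell: 497 non-cardiovascular reports, 88 non-MACE cardiovascular reports
# and 10 MACE reports of one target drug.
#
# The printed margins under-determine the joint 595-case table; the joint
# structure is filled deterministically by prefix order within each cohort
# (the first n_level cases of a cohort get the level, independently per
# variable), so the fixture is stable across versions.  Outcome codes obey
# the table's internal logic: "Unknown" death/hospitalization/
# life-threatening rows are reports with no outcome codes at all (the
# non-serious stratum), and serious reports with none of those three flags
# carry a disability code so seriousness is consistent.

TABLE1_COHORTS <- c(non_cardio = 497L, non_mace = 88L, mace = 10L)

TABLE1_COUNTS <- list(
  # level = c(non_cardio, non_mace, mace)
  sex = list(F = c(206L, 54L, 4L), M = c(143L, 25L, 5L), UNK = c(148L, 9L, 1L)),
  age = list(`30` = c(13L, 2L, 1L), `55` = c(114L, 31L, 1L),
             `70` = c(76L, 24L, 4L), `80` = c(36L, 11L, 2L),
             missing = c(258L, 20L, 2L)),
  reporter = list(MD = c(273L, 61L, 9L), PH = c(185L, 25L, 1L),
                  CN = c(39L, 2L, 0L)),
  year = list(`2021` = c(74L, 7L, 1L), `2022` = c(222L, 35L, 6L),
              `2023` = c(201L, 46L, 3L)),
  country = list(US = c(291L, 31L, 2L), JP = c(120L, 34L, 7L),
                 FR = c(67L, 15L, 1L), BR = c(17L, 8L, 0L),
                 AU = c(2L, 0L, 0L)),
  serious = c(320L, 75L, 10L),
  death = c(50L, 10L, 6L),
  hospitalization = c(172L, 55L, 5L),
  life_threatening = c(34L, 10L, 6L)
)

TABLE1_PT <- c(non_cardio = "Rash", non_mace = "Pulmonary embolism",
               mace = "Myocardial infarction")

prefix_fill <- function(n, level_counts, cohort_idx) {
  counts <- vapply(level_counts, `[[`, integer(1), cohort_idx)
  if (sum(counts) != n)
    stopf("fixture counts for cohort %d sum to %d, not %d",
          cohort_idx, sum(counts), n)
  rep(names(level_counts), counts)
}

#' Baseline-table fixture: 595 synthetic case reports
#'
#' Builds a deterministic set of 595 single-drug case reports (497
#' non-cardiovascular, 88 non-MACE cardiovascular, 10 MACE) whose per-cohort
#' marginal counts of sex, age band, reporter type, year of report,
#' reporting region, serious outcome, death, hospitalization and
#' life-threatening status each equal a fixed reference cell table.  The
#' cases are emitted through the normal ingestion path (a [raw_quarter()]
#' assembled by [assemble_cases()]) and classified with the shipped SMQ
#' mapping; every case carries a unique therapy start date, so the fixture
#' passes [deduplicate()] unchanged.
#'
#' @param as return form: `"labeled"` (default; classified with the shipped
#'   mapping and target drug names), `"cases"` (assembled, unlabeled), or
#'   `"raw"` (the `raw_quarter`).
#' @return a `faers_labeled`, `faers_cases` or `raw_quarter`.
#' @examples
#' fx <- table1_fixture()
#' sum(fx$labels$is_cardio)   # 98 cardiovascular cases
#' @export
table1_fixture <- function(as = c("labeled", "cases", "raw")) {
  as <- match.arg(as)
  cohorts <- names(TABLE1_COHORTS)
  demo_parts <- list(); outc_parts <- list(); reac_parts <- list()
  drug_parts <- list(); ther_parts <- list()
  offset <- 0L
  for (ci in seq_along(cohorts)) {
    nm <- cohorts[ci]
    n <- TABLE1_COHORTS[[nm]]
    idx <- offset + seq_len(n)
    offset <- offset + n
    case_id <- sprintf("T1%06d", idx)

    sex <- prefix_fill(n, TABLE1_COUNTS$sex, ci)
    sex[sex == "UNK"] <- ""
    age <- prefix_fill(n, TABLE1_COUNTS$age, ci)
    age_cod <- ifelse(age == "missing", "", "YR")
    age[age == "missing"] <- ""
    reporter <- prefix_fill(n, TABLE1_COUNTS$reporter, ci)
    year <- prefix_fill(n, TABLE1_COUNTS$year, ci)
    country <- prefix_fill(n, TABLE1_COUNTS$country, ci)

    n_serious <- TABLE1_COUNTS$serious[ci]
    j <- seq_len(n)
    serious <- j <= n_serious
    death <- j <= TABLE1_COUNTS$death[ci]
    hosp <- j <= TABLE1_COUNTS$hospitalization[ci]
    lt <- j <= TABLE1_COUNTS$life_threatening[ci]
    needs_ds <- serious & !death & !hosp & !lt

    demo_parts[[nm]] <- data.frame(
      primaryid = case_id, event_dt = "",
      fda_dt = paste0(year, "0701"),
      age = age, age_cod = age_cod, sex = sex, occp_cod = reporter,
      reporter_country = country, stringsAsFactors = FALSE)
    oc_id <- c(case_id[death], case_id[hosp], case_id[lt], case_id[needs_ds])
    oc_cod <- c(rep("DE", sum(death)), rep("HO", sum(hosp)),
                rep("LT", sum(lt)), rep("DS", sum(needs_ds)))
    outc_parts[[nm]] <- data.frame(primaryid = oc_id, outc_cod = oc_cod,
                                   stringsAsFactors = FALSE)
    reac_parts[[nm]] <- data.frame(primaryid = case_id, pt = TABLE1_PT[[nm]],
                                   stringsAsFactors = FALSE)
    drug_parts[[nm]] <- data.frame(primaryid = case_id, drug_seq = "1",
                                   role_cod = "PS", drugname = "AMIVANTAMAB",
                                   stringsAsFactors = FALSE)
    ther_parts[[nm]] <- data.frame(
      primaryid = case_id, dsg_drug_seq = "1",
      start_dt = format_faers_date(as.Date("2021-01-01") + idx - 1L),
      end_dt = "", stringsAsFactors = FALSE)
  }
  rq <- raw_quarter("2023Q2",
                    demo = do.call(rbind, demo_parts),
                    drug = do.call(rbind, drug_parts),
                    reac = do.call(rbind, reac_parts),
                    outc = do.call(rbind, outc_parts),
                    ther = do.call(rbind, ther_parts))
  if (as == "raw") return(rq)
  cases <- assemble_cases(rq)
  if (as == "cases") return(cases)
  label_cases(cases, drug_names = c("AMIVANTAMAB", "RYBREVANT"))
}
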