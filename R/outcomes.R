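# Baseline-characteristics table, outcome-severity breakdowns and
# chi-squared group comparisons.

AGE_BAND_LEVELS <- c("<18", "18-45", "45-65", "65-75", ">=75", "Unknown")

# Age bands are left-closed, right-open ([18,45), [45,65), [65,75)) with the
# top band closed above at 130.
age_band <- function(age_years) {
  out <- rep("Unknown", length(age_years))
  known <- !is.na(age_years)
  out[known & age_years < 18] <- "<18"
  out[known & age_years >= 18 & age_years < 45] <- "18-45"
  out[known & age_years >= 45 & age_years < 65] <- "45-65"
  out[known & age_years >= 65 & age_years < 75] <- "65-75"
  out[known & age_years >= 75 & age_years <= 130] <- ">=75"
  out
}

# Yes / No / Unknown for one outcome flag: Unknown when the report carries
# no outcome codes at all (outcome information absent, the non-serious
# stratum of spontaneous reports).
outcome_level <- function(flag, has_outcome) {
  ifelse(flag, "Yes", ifelse(has_outcome, "No", "Unknown"))
}

#' Outcome-severity summary for a group of cases
#'
#' Counts and exact proportions of death, life-threatening events,
#' hospitalization, disability and congenital anomaly over a group.
#'
#' @param labeled a `faers_labeled`.
#' @param case_ids identifiers of the group's cases (default: all).
#' @param group_id label carried into the output.
#' @return one-row data.frame with `group_id`, `n`, the five flag counts,
#'   `n_serious`, and proportions `p_death`, `p_life_threatening`,
#'   `p_hospitalization`.  An empty group yields `n = 0` and `NA`
#'   proportions.
#' @export
outcome_summary <- function(labeled, case_ids = NULL, group_id = "all") {
  stopifnot(inherits(labeled, "faers_labeled"))
  lab <- labeled$labels
  if (!is.null(case_ids)) lab <- lab[lab$case_id %in% case_ids, , drop = FALSE]
  n <- nrow(lab)
  cnt <- function(col) sum(lab[[col]])
  prop <- function(x) if (n == 0) NA_real_ else x / n
  data.frame(
    group_id = group_id, n = n,
    n_death = cnt("death"),
    n_life_threatening = cnt("life_threatening"),
    n_hospitalization = cnt("hospitalization"),
    n_disability = cnt("disability"),
    n_congenital = cnt("congenital_anomaly"),
    n_serious = cnt("is_serious"),
    p_death = prop(cnt("death")),
    p_life_threatening = prop(cnt("life_threatening")),
    p_hospitalization = prop(cnt("hospitalization")),
    stringsAsFactors = FALSE
  )
}

#' Per-SMQ outcome-severity table
#'
#' One [outcome_summary()] row per SMQ (cases in several SMQs contribute to
#' each), ordered by group size descending.
#'
#' @param labeled a `faers_labeled`.
#' @return data.frame of per-SMQ outcome summaries.
#' @export
outcome_by_smq <- function(labeled) {
  smqs <- sort(unique(labeled$memberships$smq_id))
  rows <- lapply(smqs, function(s) {
    ids <- labeled$memberships$case_id[labeled$memberships$smq_id == s]
    outcome_summary(labeled, ids, group_id = s)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

baseline_variables <- function(labeled) {
  demo <- labeled$demo
  lab <- labeled$labels
  sex_map <- c(F = "Female", M = "Male", UNK = "Unknown")
  rep_map <- c(MD = "Doctor", PH = "Pharmacist", CN = "Consumer",
               OT = "Other", UNK = "Unknown")
  list(
    sex = unname(sex_map[demo$sex]),
    age_band = age_band(demo$age_years),
    reporter = unname(rep_map[demo$occupation]),
    report_year = ifelse(is.na(demo$report_year), "Unknown",
                         as.character(demo$report_year)),
    region = ifelse(demo$region == "UNK", "Unknown", demo$region),
    serious = ifelse(lab$is_serious, "Serious", "Non-serious"),
    death = outcome_level(lab$death, lab$has_outcome),
    hospitalization = outcome_level(lab$hospitalization, lab$has_outcome),
    life_threatening = outcome_level(lab$life_threatening, lab$has_outcome)
  )
}

#' Baseline-characteristics table over analysis cohorts
#'
#' Tabulates sex, age band, reporter type, year of report, reporting
#' region, serious outcome, death, hospitalization and life-threatening
#' status across four cohorts: non-cardiovascular, any cardiovascular,
#' non-MACE cardiovascular and MACE.  Percentages are relative to the
#' cohort size including Unknown rows.  Per-variable p-values compare
#' cardiovascular vs non-cardiovascular and MACE vs non-MACE cohorts by
#' Pearson's chi-squared test; the `unknown_policy` controls whether
#' Unknown levels enter the test (they are always shown in the table).
#'
#' @param labeled a `faers_labeled`.
#' @param unknown_policy `"exclude"` (default) or `"include_as_level"`.
#' @return a `baseline_table` data.frame: one row per variable level with
#'   counts and percentages per cohort and per-variable p-values.
#' @export
baseline_table <- function(labeled, unknown_policy = c("exclude",
                                                       "include_as_level")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(labeled, "faers_labeled"))
  lab <- labeled$labels
  cohorts <- list(
    non_cardio = !lab$is_cardio,
    cardio = lab$is_cardio,
    non_mace = lab$is_cardio & !lab$is_mace,
    mace = lab$is_mace
  )
  vars <- baseline_variables(labeled)
  level_order <- list(
    sex = c("Female", "Male", "Unknown"),
    age_band = AGE_BAND_LEVELS,
    reporter = c("Doctor", "Pharmacist", "Consumer", "Other", "Unknown"),
    serious = c("Serious", "Non-serious"),
    death = c("Yes", "No", "Unknown"),
    hospitalization = c("Yes", "No", "Unknown"),
    life_threatening = c("Yes", "No", "Unknown"),
    region = c(setdiff(REGION_LEVELS, "UNK"), "Unknown")
  )
  rows <- list()
  for (v in names(vars)) {
    vals <- vars[[v]]
    levels_v <- level_order[[v]] %||% sort(unique(vals))
    levels_v <- levels_v[levels_v %in% vals]
    counts <- vapply(cohorts, function(mask) {
      vapply(levels_v, function(lv) sum(vals[mask] == lv), integer(1))
    }, integer(length(levels_v)))
    counts <- matrix(counts, nrow = length(levels_v),
                     dimnames = list(levels_v, names(cohorts)))
    ns <- vapply(cohorts, sum, integer(1))
    pct <- sweep(counts, 2, pmax(ns, 1L), "/") * 100
    pct[, ns == 0] <- NA_real_
    p_cardio <- baseline_p_value(vals, cohorts$non_cardio, cohorts$cardio,
                                 unknown_policy)
    p_mace <- baseline_p_value(vals, cohorts$non_mace, cohorts$mace,
                               unknown_policy)
    df <- data.frame(variable = v, level = levels_v,
                     n_non_cardio = counts[, "non_cardio"],
                     pct_non_cardio = pct[, "non_cardio"],
                     n_cardio = counts[, "cardio"],
                     pct_cardio = pct[, "cardio"],
                     n_non_mace = counts[, "non_mace"],
                     pct_non_mace = pct[, "non_mace"],
                     n_mace = counts[, "mace"],
                     pct_mace = pct[, "mace"],
                     p_cardio_vs_non = p_cardio,
                     p_mace_vs_non = p_mace,
                     stringsAsFactors = FALSE)
    rows[[v]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cohort_n") <- vapply(cohorts, sum, integer(1))
  class(out) <- c("baseline_table", "data.frame")
  out
}

baseline_p_value <- function(vals, mask_a, mask_b, unknown_policy) {
  lv <- sort(unique(c(vals[mask_a], vals[mask_b])))
  tab <- rbind(table(factor(vals[mask_a], levels = lv)),
               table(factor(vals[mask_b], levels = lv)))
  res <- tryCatch(
    suppressWarnings(chi_square(tab, unknown_policy = unknown_policy)),
    error = function(e) NULL
  )
  if (is.null(res)) NA_real_ else res$p_value
}

#' Pearson chi-squared comparison of group counts
#'
#' Pearson's statistic without continuity correction on a 2 x k (or r x k)
#' count table.  Levels labelled as unknown are excluded from the test
#' under the default policy while remaining reportable in tables; levels
#' with a zero marginal are dropped with a warning.
#'
#' @param counts integer matrix of counts, columns = levels (column names
#'   used to spot unknown levels), rows = groups.
#' @param unknown_policy `"exclude"` (default) or `"include_as_level"`.
#' @param unknown_labels column names treated as unknown levels.
#' @return a `group_comparison` list: `counts` (as tested), `chi2`, `df`,
#'   `p_value`, `unknown_policy`.
#' @export
chi_square <- function(counts, unknown_policy = c("exclude",
                                                  "include_as_level"),
                       unknown_labels = c("Unknown", "UNK", "unknown")) {
  unknown_policy <- match.arg(unknown_policy)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  if (unknown_policy == "exclude" && !is.null(colnames(counts))) {
    keep <- !(colnames(counts) %in% unknown_labels)
    counts <- counts[, keep, drop = FALSE]
  }
  zero_col <- colSums(counts) == 0
  zero_row <- rowSums(counts) == 0
  if (any(zero_col) || any(zero_row)) {
    warnf("dropping %d zero-margin level(s)/group(s) before the test",
          sum(zero_col) + sum(zero_row))
    counts <- counts[!zero_row, !zero_col, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stopf("need at least a 2 x 2 table after policy; got %d x %d",
          nrow(counts), ncol(counts))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(counts = counts,
                 chi2 = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 unknown_policy = unknown_policy),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> chi2 = %.4f, df = %d, p = %.4g (%s)\n",
              x$chi2, x$df, x$p_value, x$unknown_policy))
  invisible(x)
}
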