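# Time to onset (TTO): days from first target-drug therapy start to the
# reported event date, with per-SMQ quantile and cumulative-incidence
# summaries.

#' Per-case time to onset
#'
#' `days = event_date - earliest therapy_start` among the case's drug
#' entries matching the target drug, in whole days.  Missing when either
#' date is absent (partial dates count as absent: no day-level precision is
#' fabricated) and when the difference is negative, which is logged as
#' implausible via the `n_implausible` attribute.
#'
#' @param cases a `faers_cases` (or `faers_labeled`).
#' @param target_drug_names drug name list identifying the target drug
#'   entries (matched as in [match_target_drug()]).
#' @return data.frame with `case_id` and `days` (integer, `NA` when
#'   unknown); attribute `n_implausible` counts negative differences.
#' @export
compute_tto <- function(cases, target_drug_names) {
  stopifnot(inherits(cases, "faers_cases"))
  drugs <- cases$drugs
  targets <- unique(normalize_drug_name(target_drug_names))
  targets <- targets[!is.na(targets) & nzchar(targets)]
  hit <- rep(FALSE, nrow(drugs))
  for (tg in targets) {
    pattern <- paste0("(^| )", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tg),
                      "( |$)")
    hit <- hit | grepl(pattern, drugs$normalized_name)
  }
  matched <- drugs[hit & !is.na(drugs$therapy_start), , drop = FALSE]
  ids <- cases$demo$case_id
  first_start <- rep(NA_integer_, length(ids))
  if (nrow(matched) > 0) {
    mins <- tapply(as.integer(matched$therapy_start), matched$case_id, min)
    idx <- match(ids, names(mins))
    first_start <- as.integer(as.vector(mins[idx]))
  }
  days <- as.integer(as.integer(cases$demo$event_date) - first_start)
  implausible <- !is.na(days) & days < 0
  days[implausible] <- NA_integer_
  structure(data.frame(case_id = ids, days = days, stringsAsFactors = FALSE),
            n_implausible = sum(implausible))
}

#' Per-SMQ time-to-onset records
#'
#' Expands per-case TTO over SMQ memberships: a case belonging to several
#' SMQs contributes one record to each, since per-SMQ onset is summarized
#' independently.
#'
#' @param labeled a `faers_labeled`.
#' @param target_drug_names target drug name list.
#' @return data.frame with `case_id`, `smq_id`, `days`.
#' @export
tto_records <- function(labeled, target_drug_names) {
  stopifnot(inherits(labeled, "faers_labeled"))
  per_case <- compute_tto(labeled, target_drug_names)
  out <- merge(labeled$memberships, per_case, by = "case_id")
  out <- out[order(out$smq_id, out$case_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize time-to-onset for one group
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) by default; `quantile_type = 8` switches to
#' the median-unbiased convention.  Cumulative incidence at horizon `h` is
#' the share of known onsets at or before `h` days, the denominator being
#' cases with a known TTO only.
#'
#' @param days integer vector of onset days (`NA` = unknown, excluded).
#' @param horizons numeric vector of horizons in days.
#' @param quantile_type passed to [stats::quantile()].
#' @return list with `n_known`, `median_days`, `q1_days`, `q3_days`, and
#'   `cum_incidence` (named numeric, one entry per horizon).  With no known
#'   onsets the quantiles are `NA` and `empty = TRUE`.
#' @export
summarize_tto <- function(days, horizons = c(30, 90, 180), quantile_type = 7) {
  known <- days[!is.na(days)]
  ci <- vapply(horizons, function(h) {
    if (length(known) == 0) NA_real_ else mean(known <= h)
  }, numeric(1))
  names(ci) <- paste0("cuminc_", horizons)
  if (length(known) == 0) {
    return(list(n_known = 0L, median_days = NA_real_, q1_days = NA_real_,
                q3_days = NA_real_, cum_incidence = ci, empty = TRUE))
  }
  q <- unname(stats::quantile(known, probs = c(0.25, 0.5, 0.75),
                              type = quantile_type))
  list(n_known = length(known), median_days = q[2], q1_days = q[1],
       q3_days = q[3], cum_incidence = ci, empty = FALSE)
}

#' Per-SMQ time-to-onset summary table
#'
#' @param records data.frame from [tto_records()].
#' @param horizons numeric vector of horizons in days.
#' @param quantile_type passed to [stats::quantile()].
#' @return data.frame: one row per SMQ with `n_known`, `median_days`,
#'   `q1_days`, `q3_days` and one `cuminc_<h>` column per horizon.
#' @export
summarize_tto_by_smq <- function(records, horizons = c(30, 90, 180),
                                 quantile_type = 7) {
  smqs <- sort(unique(records$smq_id))
  rows <- lapply(smqs, function(s) {
    sm <- summarize_tto(records$days[records$smq_id == s], horizons,
                        quantile_type)
    cbind(data.frame(smq_id = s, n_known = sm$n_known,
                     median_days = sm$median_days, q1_days = sm$q1_days,
                     q3_days = sm$q3_days, stringsAsFactors = FALSE),
          as.data.frame(as.list(sm$cum_incidence)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
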