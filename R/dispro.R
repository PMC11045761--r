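# Case/non-case contingency tables and ROR / shrinkage-IC disproportionality
# statistics with signal flagging.
#
# ROR = ad/bc with an ln-scale Wald 95% CI
#   exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d));
# IC = log2((a + 0.5) / (E + 0.5)) with E = (a+b)(a+c)/N, the +0.5 terms
# shrinking small-count estimates toward zero.  Two interval forms for the
# IC are provided: a Wald-type interval on the log2 scale (default) and the
# Noren credible-interval approximation.

#' Build a case/non-case contingency table
#'
#' Counts the 2x2 table for one drug-event pair over a labeled case set:
#' `a` target drug & event, `b` target drug & other events, `c` other drugs
#' & event, `d` neither.  `event_id` may be an SMQ id declared by the
#' labeling mapping, or (otherwise) a reaction PT matched
#' case-insensitively.  Two counting units are supported: `"report"`, where
#' the unit is a case, and `"event_pair"` (default), where the unit is a
#' distinct (case, PT) pair so that `a + b` counts the total adverse events
#' reported for the target drug rather than the number of reports.
#'
#' @param labeled a `faers_labeled` with an `is_target` column (see
#'   [label_cases()] with `drug_names`).
#' @param event_id SMQ id or PT term.
#' @param counting_unit `"event_pair"` or `"report"`.
#' @return a `contingency_table`: list with `a`, `b`, `c`, `d`, `n`,
#'   `event_id`, `counting_unit`.
#' @export
build_contingency <- function(labeled, event_id,
                              counting_unit = c("event_pair", "report")) {
  counting_unit <- match.arg(counting_unit)
  stopifnot(inherits(labeled, "faers_labeled"))
  if (is.null(labeled$labels$is_target))
    stopf("labeled cases carry no is_target flag; label with drug_names")
  labels <- labeled$labels
  is_smq <- event_id %in% smq_ids(labeled$smq_mapping)

  if (counting_unit == "report") {
    target <- labels$is_target
    if (is_smq) {
      event <- labels$case_id %in%
        labeled$memberships$case_id[labeled$memberships$smq_id == event_id]
    } else {
      pts <- labeled$reactions
      event <- labels$case_id %in%
        pts$case_id[tolower(pts$pt) == tolower(event_id)]
    }
    a <- sum(target & event); b <- sum(target & !event)
    c_ <- sum(!target & event); d <- sum(!target & !event)
  } else {
    pairs <- unique(data.frame(case_id = labeled$reactions$case_id,
                               pt_folded = tolower(labeled$reactions$pt),
                               stringsAsFactors = FALSE))
    pair_target <- pairs$case_id %in% labels$case_id[labels$is_target]
    if (is_smq) {
      smq_pts <- labeled$smq_mapping$pt_folded[
        labeled$smq_mapping$smq_id == event_id]
      pair_event <- pairs$pt_folded %in% smq_pts
    } else {
      pair_event <- pairs$pt_folded == tolower(event_id)
    }
    a <- sum(pair_target & pair_event); b <- sum(pair_target & !pair_event)
    c_ <- sum(!pair_target & pair_event); d <- sum(!pair_target & !pair_event)
  }
  n <- a + b + c_ + d
  if (n == 0) stopf("empty contingency table for event '%s'", event_id)
  if (a + b == 0)
    stopf("no target-drug %ss in the cohort: contingency for '%s' undefined",
          if (counting_unit == "report") "case" else "event pair", event_id)
  structure(list(a = a, b = b, c = c_, d = d, n = n, event_id = event_id,
                 counting_unit = counting_unit),
            class = "contingency_table")
}

#' Construct a contingency table from counts
#' @param a,b,c,d nonnegative counts (target&event, target only, event only,
#'   neither).
#' @param event_id optional label.
#' @param counting_unit `"report"` or `"event_pair"`.
#' @return a `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, event_id = NA_character_,
                              counting_unit = "report") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 event_id = event_id, counting_unit = counting_unit),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s (%s): a=%d b=%d c=%d d=%d (N=%d)\n",
              x$event_id, x$counting_unit, x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

# Vectorized cores shared by the scalar wrappers and the bulk simulation
# path.  Zero cells make the ROR undefined (NA) unless continuity-corrected.
ror_core <- function(a, b, c, d, conf_level = 0.95, continuity = FALSE) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (continuity) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    zero <- rep(FALSE, length(a))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(ror) - z * se)
  hi <- exp(log(ror) + z * se)
  ror[zero] <- lo[zero] <- hi[zero] <- NA_real_
  list(ror = ror, ror025 = lo, ror975 = hi, zero_cell = zero)
}

ic_core <- function(a, b, c, d, ci_method = c("wald_ic", "noren_credible")) {
  ci_method <- match.arg(ci_method)
  n <- a + b + c + d
  expected <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (expected + 0.5))
  if (ci_method == "wald_ic") {
    half <- stats::qnorm(0.975) * (1 / log(2)) / sqrt(a + 0.5)
    lo <- ic - half
    hi <- ic + half
  } else {
    s <- a + 0.5
    lo <- ic - 3.3 * s^(-0.5) - 2 * s^(-1.5)
    hi <- ic + 2.4 * s^(-0.5) - 0.5 * s^(-1.5)
  }
  list(ic = ic, ic025 = lo, ic975 = hi, expected = expected)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = ad/bc`; the 95% CI is computed on the natural-log scale as
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  Any zero cell makes
#' the estimate undefined: the result carries `NA`s and
#' `reason = "zero_cell"` rather than raising an error.  No continuity
#' correction is applied by default; `continuity = TRUE` adds 0.5 to every
#' cell (Haldane-Anscombe).
#'
#' @param table a `contingency_table`.
#' @param conf_level confidence level (default 0.95).
#' @param continuity add 0.5 to all cells instead of returning undefined.
#' @return list with `ror`, `ror025`, `ror975`, and `reason`
#'   (`NA` or `"zero_cell"`).
#' @export
ror_with_ci <- function(table, conf_level = 0.95, continuity = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  r <- ror_core(table$a, table$b, table$c, table$d, conf_level, continuity)
  list(ror = r$ror, ror025 = r$ror025, ror975 = r$ror975,
       reason = if (r$zero_cell) "zero_cell" else NA_character_)
}

#' Shrinkage information component with interval
#'
#' `IC = log2((a + 0.5) / (E + 0.5))` with expected count
#' `E = (a+b)(a+c)/N`; the +0.5 shrinkage keeps the statistic defined and
#' conservative at `a = 0`.  Interval methods: `"wald_ic"` (default), a
#' symmetric Wald-type interval `IC +/- 1.96/ln(2) * (a+0.5)^(-1/2)` on the
#' log2 scale; or `"noren_credible"`, the asymmetric credible-interval
#' approximation `IC025 = IC - 3.3(a+0.5)^(-1/2) - 2(a+0.5)^(-3/2)`,
#' `IC975 = IC + 2.4(a+0.5)^(-1/2) - 0.5(a+0.5)^(-3/2)`.
#'
#' @param table a `contingency_table`.
#' @param ci_method `"wald_ic"` or `"noren_credible"`.
#' @return list with `ic`, `ic025`, `ic975`, `expected`.
#' @export
ic_with_ci <- function(table, ci_method = c("wald_ic", "noren_credible")) {
  stopifnot(inherits(table, "contingency_table"))
  ic_core(table$a, table$b, table$c, table$d, ci_method)
}

#' Signal criterion
#'
#' A drug-event pair is flagged as a signal when it has at least
#' `min_count` observed reports and either the lower ROR bound exceeds 1 or
#' the lower IC bound exceeds 0.
#'
#' @param result list or one-row data.frame with `a`, `ror025`, `ic025`.
#' @param min_count minimum observed count `a` (default 3).
#' @return logical flag.
#' @export
flag_signal <- function(result, min_count = 3) {
  stopifnot(min_count >= 0)
  ror_ok <- !is.na(result$ror025) & result$ror025 > 1
  ic_ok <- !is.na(result$ic025) & result$ic025 > 0
  result$a >= min_count & (ror_ok | ic_ok)
}

#' Disproportionality screen over SMQs and PTs
#'
#' Builds the contingency table and computes ROR, IC and the signal flag
#' for every SMQ declared in the labeling mapping and every PT in
#' `pt_list`.  Results are sorted by observed count `a` descending with a
#' stable tie-break on the event id, so the screen is deterministic.
#'
#' @param labeled a `faers_labeled` with target flags.
#' @param pt_list optional character vector of PTs to screen alongside the
#'   SMQs.
#' @param counting_unit,ci_method,min_count,continuity see
#'   [build_contingency()], [ic_with_ci()], [flag_signal()],
#'   [ror_with_ci()].
#' @return a `signal_screen` data.frame: one row per event with columns
#'   `event_id`, `event_type`, `a`, `b`, `c`, `d`, `expected`, `ror`,
#'   `ror025`, `ror975`, `ror_reason`, `ic`, `ic025`, `ic975`, `signal`.
#' @export
run_screen <- function(labeled, pt_list = NULL,
                       counting_unit = c("event_pair", "report"),
                       ci_method = c("wald_ic", "noren_credible"),
                       min_count = 3, continuity = FALSE) {
  counting_unit <- match.arg(counting_unit)
  ci_method <- match.arg(ci_method)
  events <- data.frame(event_id = smq_ids(labeled$smq_mapping),
                       event_type = "smq", stringsAsFactors = FALSE)
  if (!is.null(pt_list) && length(pt_list) > 0)
    events <- rbind(events, data.frame(event_id = pt_list, event_type = "pt",
                                       stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    tab <- build_contingency(labeled, events$event_id[i], counting_unit)
    r <- ror_with_ci(tab, continuity = continuity)
    ic <- ic_with_ci(tab, ci_method = ci_method)
    data.frame(event_id = events$event_id[i], event_type = events$event_type[i],
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               expected = ic$expected,
               ror = r$ror, ror025 = r$ror025, ror975 = r$ror975,
               ror_reason = r$reason,
               ic = ic$ic, ic025 = ic$ic025, ic975 = ic$ic975,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$signal <- flag_signal(out, min_count = min_count)
  out <- out[order(-out$a, out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_screen", "data.frame")
  out
}
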