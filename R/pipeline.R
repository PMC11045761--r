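# End-to-end orchestration: quarters -> cases -> target matching -> dedup ->
# classification -> disproportionality / TTO / outcome tables, with a
# screening-flow log mirroring a study flow diagram.

#' Pipeline run configuration
#'
#' Validates every option before any computation.  `quarters` names the
#' input: a character vector of quarter directories named by their
#' `"YYYYQn"` labels.
#'
#' @param quarters named character vector: `names()` are quarter labels,
#'   values are directories holding the quarter's files.
#' @param drug_names target drug names (generic plus brands).
#' @param smq_mapping_path PT-to-SMQ mapping file (`NULL` = shipped default).
#' @param mace_smqs SMQ ids forming the MACE composite.
#' @param counting_unit,ci_method,min_count,continuity screen options, see
#'   [run_screen()].
#' @param horizons cumulative-incidence horizons in days.
#' @param quantile_type TTO quantile convention, see [summarize_tto()].
#' @param unknown_policy chi-squared handling of Unknown levels, see
#'   [chi_square()].
#' @param report_year_source `"fda_dt"` or `"event_dt"`, see
#'   [assemble_cases()].
#' @param roles optional drug role restriction for target matching.
#' @param dialect a [faers_dialect()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(quarters,
                       drug_names = c("AMIVANTAMAB", "RYBREVANT"),
                       smq_mapping_path = NULL,
                       mace_smqs = default_mace_smqs(),
                       counting_unit = c("event_pair", "report"),
                       ci_method = c("wald_ic", "noren_credible"),
                       min_count = 3, continuity = FALSE,
                       horizons = c(30, 90, 180), quantile_type = 7,
                       unknown_policy = c("exclude", "include_as_level"),
                       report_year_source = c("fda_dt", "event_dt"),
                       roles = NULL, dialect = faers_dialect()) {
  stopifnot(length(quarters) > 0, !is.null(names(quarters)),
            all(nzchar(names(quarters))), length(drug_names) > 0,
            min_count >= 0, all(horizons >= 0),
            quantile_type %in% 1:9)
  structure(list(
    quarters = quarters, drug_names = drug_names,
    smq_mapping_path = smq_mapping_path, mace_smqs = mace_smqs,
    counting_unit = match.arg(counting_unit),
    ci_method = match.arg(ci_method),
    min_count = min_count, continuity = continuity,
    horizons = horizons, quantile_type = quantile_type,
    unknown_policy = match.arg(unknown_policy),
    report_year_source = match.arg(report_year_source),
    roles = roles, dialect = dialect), class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Reads and assembles all configured quarters, flags target-drug cases,
#' deduplicates the target stratum, classifies reactions into SMQs, and
#' produces the signal screen, per-SMQ time-to-onset summaries, per-SMQ
#' outcome-severity table and the baseline-characteristics table.  The
#' non-target reports form the disproportionality background.  The
#' screening flow (loaded, drug-matched, duplicates removed, included,
#' cardio / non-cardio) is logged and returned.  Deterministic given the
#' config and inputs.
#'
#' @param config a [run_config()]; alternatively pass `cases` directly.
#' @param cases optional pre-assembled `faers_cases` (skips file reading;
#'   used for fixtures and simulations already in memory).
#' @param quiet suppress per-stage log messages.
#' @return a `run_report` list: `flow`, `signals`, `tto`, `outcomes`,
#'   `baseline`, `smq_overlap`, and `provenance`.
#' @export
run_pipeline <- function(config, cases = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  if (is.null(cases)) {
    quarters <- lapply(names(config$quarters), function(lb)
      read_quarter(config$quarters[[lb]], lb, config$dialect))
    cases <- assemble_cases(quarters, config$dialect,
                            config$report_year_source)
  }
  n_loaded <- n_cases(cases)
  say("loaded: %d case reports", n_loaded)

  matched <- match_target_drug(cases, config$drug_names, config$roles)
  n_matched <- sum(matched)
  if (n_matched == 0) {
    stopf(paste0("no target-drug cases matched ",
                 "(flow: loaded=%d, matched=0); check drug_names"), n_loaded)
  }
  say("target drug matched: %d case reports", n_matched)

  target_cases <- subset_cases(cases, cases$demo$case_id[matched])
  dd <- deduplicate(target_cases)
  n_included <- n_cases(dd$cases)
  say("duplicates removed: %d; included: %d", dd$removed_count, n_included)

  background_cases <- subset_cases(cases, cases$demo$case_id[!matched])
  analysis <- if (n_cases(background_cases) > 0) {
    combine_cases(dd$cases, background_cases)
  } else dd$cases

  mapping <- load_smq_mapping(config$smq_mapping_path)
  labeled <- label_cases(analysis, mapping, config$mace_smqs,
                         drug_names = config$drug_names, roles = config$roles)
  target_labels <- labeled$labels[labeled$labels$is_target, , drop = FALSE]
  n_cardio <- sum(target_labels$is_cardio)
  say("cardiovascular: %d; non-cardiovascular: %d",
      n_cardio, n_included - n_cardio)

  signals <- run_screen(labeled, counting_unit = config$counting_unit,
                        ci_method = config$ci_method,
                        min_count = config$min_count,
                        continuity = config$continuity)
  say("signal screen: %d events, %d flagged", nrow(signals),
      sum(signals$signal))

  target_labeled <- label_cases(dd$cases, mapping, config$mace_smqs,
                                drug_names = config$drug_names,
                                roles = config$roles)
  tto <- summarize_tto_by_smq(
    tto_records(target_labeled, config$drug_names),
    horizons = config$horizons, quantile_type = config$quantile_type)
  outcomes <- outcome_by_smq(target_labeled)
  baseline <- baseline_table(target_labeled, config$unknown_policy)

  flow <- c(loaded = n_loaded, drug_matched = n_matched,
            duplicates_removed = dd$removed_count, included = n_included,
            cardio = n_cardio, non_cardio = n_included - n_cardio)
  structure(list(
    flow = flow, signals = signals, tto = tto, outcomes = outcomes,
    baseline = baseline,
    smq_overlap = attr(mapping, "overlap_pts"),
    provenance = list(
      package = "faersignal",
      version = as.character(utils::packageVersion("faersignal")),
      config = config[setdiff(names(config), "dialect")])),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  flow: ",
      paste(sprintf("%s=%d", names(x$flow), x$flow), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  signals flagged: %d of %d events screened\n",
              sum(x$signals$signal), nrow(x$signals)))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits the signal, TTO, outcome and baseline tables as tab-delimited
#' files plus a JSON bundle (`report.json`) of everything, including the
#' flow counts and provenance.  No timestamps are embedded, so identical
#' runs produce byte-identical output.
#'
#' @param report a `run_report`.
#' @param output_dir destination directory (created if absent).
#' @return invisibly, the files written.
#' @export
write_run_report <- function(report, output_dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_tab <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    path
  }
  files <- c(
    write_tab(report$signals, "signals.tsv"),
    write_tab(report$tto, "tto.tsv"),
    write_tab(report$outcomes, "outcomes.tsv"),
    write_tab(report$baseline, "baseline.tsv"))
  json_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(
    list(flow = as.list(report$flow),
         signals = report$signals, tto = report$tto,
         outcomes = report$outcomes, baseline = report$baseline,
         provenance = report$provenance),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(c(files, json_path))
}
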