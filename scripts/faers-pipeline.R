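#!/usr/bin/env Rscript
# Thin command-line wrapper over the faersignal package.
#
#   Rscript scripts/faers-pipeline.R run --data-dir DIR --quarters 2022Q4,2023Q1 \
#       --drug-names AMIVANTAMAB,RYBREVANT --out results/run
#   Rscript scripts/faers-pipeline.R simulate --n-target 2000 --n-background 100000 \
#       --seed 1 --out results/sim
#   Rscript scripts/faers-pipeline.R fixture --out results/fixture

suppressMessages({
  library(optparse)
  library(faersignal)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "simulate", "fixture")) {
  stop("usage: faers-pipeline.R <run|simulate|fixture> [options]", call. = FALSE)
}
cmd <- args[1]
rest <- args[-1]

if (cmd == "run") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--data-dir", type = "character", dest = "data_dir"),
    make_option("--quarters", type = "character"),
    make_option("--drug-names", type = "character", dest = "drug_names",
                default = "AMIVANTAMAB,RYBREVANT"),
    make_option("--smq-mapping", type = "character", dest = "smq_mapping",
                default = NULL),
    make_option("--counting-unit", type = "character", dest = "counting_unit",
                default = "event_pair"),
    make_option("--ci-method", type = "character", dest = "ci_method",
                default = "wald_ic"),
    make_option("--min-count", type = "integer", dest = "min_count", default = 3L),
    make_option("--out", type = "character", default = "results/run"))),
    args = rest)
  labels <- strsplit(o$quarters, ",")[[1]]
  quarters <- setNames(rep(o$data_dir, length(labels)), labels)
  rc <- run_config(quarters = quarters,
                   drug_names = strsplit(o$drug_names, ",")[[1]],
                   smq_mapping_path = o$smq_mapping,
                   counting_unit = o$counting_unit, ci_method = o$ci_method,
                   min_count = o$min_count)
  rep <- run_pipeline(rc)
  write_run_report(rep, o$out)
  print(rep)
} else if (cmd == "simulate") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--n-target", type = "integer", dest = "n_target", default = 2000L),
    make_option("--n-background", type = "integer", dest = "n_background",
                default = 100000L),
    make_option("--duplicate-rate", type = "double", dest = "duplicate_rate",
                default = 0.05),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--quarter", type = "character", default = "2023Q1"),
    make_option("--out", type = "character", default = "results/sim"))),
    args = rest)
  cfg <- sim_config(n_background = o$n_background, n_target = o$n_target,
                    duplicate_rate = o$duplicate_rate, seed = o$seed)
  sim <- generate_reports(cfg, quarter_label = o$quarter)
  write_quarter(sim$quarter, o$out)
  jsonlite::write_json(
    list(true_ror = as.list(sim$truth$true_ror),
         true_tto_median = as.list(sim$truth$true_tto_median),
         injected_duplicates = sim$truth$injected_duplicates),
    file.path(o$out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("wrote synthetic quarter %s (%d reports) to %s",
                  o$quarter, o$n_target + o$n_background, o$out))
} else {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character", default = "results/fixture"))),
    args = rest)
  write_quarter(table1_fixture(as = "raw"), o$out)
  rc <- run_config(quarters = c("2023Q2" = o$out))
  rep <- run_pipeline(rc, cases = table1_fixture(as = "cases"), quiet = TRUE)
  write_run_report(rep, o$out)
  message(sprintf("wrote fixture quarter and report tables to %s", o$out))
}
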