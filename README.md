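# faersignal

Disproportionality signal detection for FAERS-style spontaneous
adverse-event reports.

Spontaneous reporting databases (FAERS and its siblings) are the first
place post-marketing drug toxicity shows up, and the standard way to mine
them is a case/non-case analysis: for a target drug and an adverse-event
grouping, count the 2×2 table

|                | event `E` | other events |
|----------------|-----------|--------------|
| target drug    | a         | b            |
| all other drugs| c         | d            |

and ask whether the event is reported disproportionally often with the
drug. `faersignal` implements the full pipeline for pharmacovigilance
analysts and methods researchers:

* **Ingestion** — reads/writes the quarterly `$`-delimited ASCII tables
  (DEMO, DRUG, REAC, OUTC, THER) and joins them into normalized case
  reports (`read_quarter()`, `assemble_cases()`).
* **Cleaning** — rule-based deduplication on sex, age, country, reaction
  set, drug set and therapy dates (`deduplicate()`); generic+brand-name
  target-drug matching (`match_target_drug()`).
* **Classification** — custom SMQ groupings from a user-supplied
  PT-to-SMQ mapping, MACE composite, seriousness flags (`label_cases()`).
* **Statistics** — reporting odds ratio `ROR = ad/bc` with Wald 95% CI
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`, and the shrinkage information
  component `IC = log2((a+0.5)/(E+0.5))`, `E = (a+b)(a+c)/N`, with Wald or
  Norén-style intervals; a pair is a *signal* when `a ≥ 3` and
  `ROR025 > 1` or `IC025 > 0` (`run_screen()`, `ror_with_ci()`,
  `ic_with_ci()`, `flag_signal()`).
* **Description** — time-to-onset quartiles and cumulative incidence per
  SMQ (`compute_tto()`, `summarize_tto_by_smq()`), outcome-severity and
  baseline-characteristics tables with chi-squared comparisons
  (`baseline_table()`, `outcome_by_smq()`, `chi_square()`).
* **Synthetic data** — a generator with recorded ground truth
  (`generate_reports()`, `simulate_screen_counts()`,
  `inject_duplicates()`) and a deterministic 595-case fixture
  (`table1_fixture()`) so every stage is testable without downloading
  anything.

The shipped PT-to-SMQ mapping
(`inst/extdata/smq_cardiovascular_synthetic.tsv`) defines 11
cardiovascular groupings with **constructed placeholder** PT lists —
MedDRA content is licensed and cannot be redistributed — so real analyses
should pass their own mapping file.

## Worked example

Generate a synthetic cohort with known enrichment (venous thrombotic
diseases ×12, abnormal blood pressure ×1.8, arrhythmia ×2.4, pericardial
effusion ×3), write it as FAERS-style quarterly files, and run the
pipeline:

```r
library(faersignal)

cfg <- sim_config(n_background = 20000, n_target = 1500, seed = 8)
sim <- generate_reports(cfg, quarter_label = "2023Q1")
dir <- file.path(tempdir(), "q"); write_quarter(sim$quarter, dir)

rc  <- run_config(quarters = c("2023Q1" = dir),
                  drug_names = "AMIVANTAMAB", counting_unit = "report")
rep <- run_pipeline(rc)
#> loaded: 22575 case reports
#> target drug matched: 1576 case reports
#> duplicates removed: 76; included: 1500
#> cardiovascular: 157; non-cardiovascular: 1343
#> signal screen: 11 events, 5 flagged

head(rep$signals[, c("event_id", "a", "expected", "ror", "ror025",
                     "ror975", "ic", "ic025", "signal")], 5)
#>                     event_id  a expected   ror ror025 ror975    ic ic025 signal
#> 1 venous_thrombotic_diseases 69    10.47 11.46   8.32  15.77 2.664 2.325   TRUE
#> 2    abnormal_blood_pressure 38    20.73  1.97   1.40   2.78 0.858 0.403   TRUE
#> 3                 arrhythmia 25    12.53  2.17   1.42   3.31 0.968 0.408   TRUE
#> 4                     stroke 10     4.53  2.42   1.24   4.75 1.061 0.188   TRUE
#> 5       pericardial_effusion  8     2.60  3.63   1.66   7.90 1.455 0.485   TRUE
```

Reading: 69 target-drug reports fell in the venous-thrombotic grouping
against 10.5 expected under independence, ROR 11.5 (8.3–15.8) — close to
the generating odds ratio 12.55 recorded in `sim$truth$true_ror`. The four
enriched groupings are all flagged; `stroke` (generated at ratio 1) is a
borderline false positive of the kind a 5%-level criterion produces — the
screen generates hypotheses, it does not confirm them. Onset timing per
grouping:

```r
head(rep$tto[, 1:5], 2)
#>                    smq_id n_known median_days q1_days q3_days
#> 1 abnormal_blood_pressure      36        40.5   16.50    74.2
#> 2              arrhythmia      24         7.0    3.75    13.5
```

The deterministic fixture reproduces a published-style baseline table
exactly; for instance the outcome severity of its cardiovascular cohort:

```r
fx <- table1_fixture()
outcome_summary(fx, fx$labels$case_id[fx$labels$is_cardio], "cardio")
#>   group_id  n n_death p_death p_hospitalization
#> 1   cardio 98      16   0.163             0.612
```

i.e. death in 16.3% and hospitalization in 61.2% of the 98 cardiovascular
cases.

A thin CLI wrapper is provided in `scripts/faers-pipeline.R`
(subcommands `run`, `simulate`, `fixture`).

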