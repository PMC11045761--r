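---
title: "Disproportionality signal detection on spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect voluntary
reports of suspected drug reactions. They have no denominator: we observe
reports, not exposed patients, so incidence cannot be estimated. What can be
estimated is *disproportionality* — whether a particular adverse event is
reported relatively more often with the drug of interest than with all other
drugs. `faersignal` implements this case/non-case analysis end to end for a
target drug and a set of custom event groupings (standardized MedDRA
queries, SMQs), together with the descriptive layers that usually accompany
it: a deduplication step, time-to-onset (TTO) summaries, outcome-severity
breakdowns and a baseline-characteristics table.

The motivating use case is cardiovascular toxicity surveillance for a
bispecific EGFR/MET antibody used in non-small-cell lung cancer, screened
against eleven custom cardiovascular SMQs (venous thrombotic diseases,
abnormal blood pressure, arrhythmia, pericardial effusion, cardiac failure,
stroke, sudden death, coronary artery disease, myocardial injury,
peripheral vascular disease, and a residual cardiomyopathy grouping), but
every drug name, SMQ definition and threshold is configuration.

## The statistics

For one drug–event pair the data reduce to a 2×2 table: `a` reports with
the target drug and the event, `b` with the drug and other events, `c`
with other drugs and the event, `d` the remainder, `N = a+b+c+d`.

**Reporting odds ratio.** `ROR = ad/bc`, with a Wald 95% interval on the
log scale,

```
ROR_{025,975} = exp( ln(ad/bc) ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d) ).
```

Any zero cell leaves the ROR undefined; the result then carries an explicit
`zero_cell` reason rather than a value. A Haldane–Anscombe +0.5 continuity
correction is available behind a flag but off by default, so the default
estimate is never silently corrected.

**Information component.** With expected count `E = (a+b)(a+c)/N`,

```
IC = log2( (a + 0.5) / (E + 0.5) ).
```

The +0.5 shrinkage terms keep the statistic finite and pull small-count
estimates toward zero; at `a = 0` the IC is negative by construction. Two
interval forms are implemented and selectable:

* `wald_ic` (default): `IC ± 1.96/ln(2) · (a+0.5)^(-1/2)`, a symmetric
  Wald-type interval on the log2 scale;
* `noren_credible`: the asymmetric credible-interval approximation
  `IC025 = IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2)`,
  `IC975 = IC + 2.4(a+0.5)^(−1/2) − 0.5(a+0.5)^(−3/2)`.

The Wald form was made the default because published screens of this kind
typically show symmetric IC intervals with half-width
`≈ 2.83/sqrt(a+0.5)`, which is what this form produces; the credible
approximation is retained because it is the standard in the shrinkage
literature. Both are documented, neither is claimed to be the only
legitimate choice.

**Signal criterion.** An event is flagged when `a ≥ min_count` (default 3)
and either `ROR025 > 1` or `IC025 > 0`. The count gate is applied to the
*observed* count; the expected count `E` is reported alongside for
transparency, since some practice gates on `E` instead. Both are visible in
the screen output and the gate is configurable.

**Counting unit.** By default the screen counts distinct (case, PT) pairs
(`event_pair`), so `a + b` is the total number of adverse events reported
for the drug rather than the number of reports; `report` mode (one unit per
case) is provided for sensitivity analysis and is the unit used in the
package's simulation checks, where its binomial structure is exact.

## Data handling rules

**Dialect.** The reader speaks the post-2014 quarterly ASCII layout
(`$`-delimited, `primaryid` keys); other layouts are accommodated by
remapping column names in `faers_dialect()`, not by editing the parser.

**Partial dates.** Spontaneous reports often carry year- or month-precision
dates. A partial date retains its year (used for the year-of-report table)
but yields no day-level `Date`, so TTO arithmetic never fabricates
precision; such cases are simply unknown-onset. Which date anchors the year
of report (FDA receipt date vs event date) is a config choice,
`report_year_source`, defaulting to the receipt date because it is far less
often missing.

**Deduplication.** Two reports are duplicates when they agree on all of:
sex, age in years, reporting country, the sorted set of reaction PTs, the
sorted set of normalized drug names, and the sorted sets of therapy start
and end dates. Missing components compare equal via an explicit missing
token — necessary in data where half the ages may be absent. The retained
representative is the lexicographically greatest case id, a deterministic
proxy for "latest version" under FAERS id conventions. Sets (not single
values) are compared because reports are multi-drug and multi-PT; per-row
keys would over-delete.

**Drug matching.** Names are normalized (upper case, punctuation collapsed)
and matched by equality or whole-word containment, so `RYBREVANT 350MG`
matches `RYBREVANT`. Role codes are not filtered by default — suspect and
concomitant mentions both count — with an optional restriction to
primary/secondary suspects.

**Classification.** SMQ membership is case-insensitive PT-set
intersection. The MACE composite defaults to
{cardiac failure, stroke, sudden death, coronary artery disease,
myocardial injury}; composites of this kind are rarely reported with their
exact member list, so the set is explicit configuration, not a constant.
The shipped PT-to-SMQ mapping is a *constructed placeholder*
(`inst/extdata/smq_cardiovascular_synthetic.tsv`, labelled synthetic):
licensed MedDRA content cannot be redistributed, so real analyses must
supply their own mapping file in the same three-column format.

**TTO.** Onset is `event date − earliest therapy start among target-drug
entries`, in whole days; negative differences are implausible and become
unknown (counted). Quantiles use the linear-interpolation convention
(`stats::quantile` type 7), switchable, because integer-valued published
quartiles cannot disambiguate the convention. Cumulative incidence at a
horizon divides by cases with *known* onset only — the only denominator
under which "100% within 90 days" claims are meaningful when some dates
are missing.

**Baseline table.** Age bands are `[18,45)`, `[45,65)`, `[65,75)`,
`[75,130]`; "health professional" aggregates doctor and pharmacist
reporter codes; percentages divide by the full cohort size including
Unknown rows. For the death / hospitalization / life-threatening rows,
"Unknown" means the report carries no outcome codes at all, which makes
the Unknown row equal the non-serious stratum — the internal consistency
rule the fixture (below) relies on. Chi-squared comparisons exclude
Unknown levels by default (`unknown_policy`), which is standard practice;
the p-values are descriptive either way since no multiplicity adjustment
is applied (none is conventional in this setting).

## The synthetic generator

`generate_reports()` emulates the structure the pipeline consumes, with
every generating quantity recorded as ground truth:

* a background stratum and a target-drug stratum; within each report every
  SMQ fires independently as Bernoulli with probability
  `baseline × (rr if target)`, one representative PT drawn per hit (from
  the SMQ's first `pt_per_smq` mapping terms, so PT-level signals can be
  concentrated), plus 1–3 background PTs so no report is reaction-free;
* demographics with configurable sex/country/occupation distributions and
  ~40% missing age by default;
* therapy-start dates uniform over a 2019–2023 window, event dates equal
  to start plus a per-SMQ onset delay (Weibull by default, medians from
  about a week to over a year across the cardiovascular groupings), a
  configurable fraction of event dates degraded to month precision;
* per-SMQ outcome-code probabilities (death ≈ 16%, hospitalization ≈ 55%
  for cardiovascular hits by default, lower in the background);
* field-identical duplicates injected at a configurable rate (default 5%).

The recorded true ROR uses the odds identity
`(p_t/(1−p_t)) / (p_b/(1−p_b))`, not the raw ratio `rr`, so recovery tests
compare like with like.

What the generator does **not** emulate: drug co-prescription structure,
masking/competition between signals, reporting delay dynamics, duplicate
records that differ in a field (real duplicates are often near-matches),
or PT misspellings. Tests passing on this generator therefore demonstrate
the pipeline's correctness under its own model — counting, statistics,
recovery — not robustness to the full messiness of real spontaneous data.

For many-seed operating characteristics, `simulate_screen_counts()` draws
the per-SMQ contingency counts directly from the same law
(`a ~ Bin(n_target, p_t)`, `c ~ Bin(n_background, p_b)`), which is
distributionally identical to generating every report and counting in
report mode; this makes 500-cohort type-I/power estimates run in
milliseconds. The per-report generator is still exercised by the recovery
and end-to-end checks.

## The 595-case fixture

`table1_fixture()` builds a deterministic set of 595 single-drug reports —
497 non-cardiovascular, 88 non-MACE cardiovascular, 10 MACE — whose
per-cohort marginal counts of sex, age band, reporter type, year, region,
seriousness, death, hospitalization and life-threatening status equal a
fixed reference cell table. Printed margins under-determine the joint
distribution; the joint is filled by deterministic prefix order within
each cohort (the first *k* cases of a cohort carry a level, independently
per variable), serious reports lacking all three tabulated flags receive a
disability code so seriousness stays consistent, and every case gets a
unique therapy-start date so the fixture passes deduplication unchanged.
Cell medians of continuous age are *not* reproduced — only band counts
are, since only counts are margin-checkable. The fixture is emitted
through the normal raw-file assembly path, so it also exercises ingestion.

## Problem sizes and tolerances in the test suite

The suite checks, among others: exact fixture proportions (integer
arithmetic); ROR/IC against direct closed-form evaluation on 1,000 random
tables at `1e-9`; contingency counting against brute-force double loops on
cohorts of up to 50 cases; type-I control of the `ROR025 > 1` flag at true
ROR 1 over 500 simulated cohorts of 2,000 target / 100,000 background
reports (bound `5% + 2·SE`); ≥95% detection of a 10× reporting ratio at an
expected count of ~50; geometric-mean ROR recovery within 10% of truth
over eight 55,000-report cohorts; TTO median recovery within four
median-standard-errors (+1 day for whole-day discretization) of the true
Weibull median at ~550 known onsets; exact removal of duplicates injected
at rate 0.1 into 1,000 key-distinct cases; and byte-identical
write→read→write round trips. These sizes were chosen to give the
operating-characteristic checks comfortable Monte-Carlo margins while
keeping the whole suite around a minute on one core.

## Known limitations

* Disproportionality is hypothesis-generating only: no denominators, no
  causality, and reporting biases (stimulated reporting, channeling) move
  RORs in ways no statistic corrects.
* The shipped SMQ mapping is a placeholder; results are only as meaningful
  as the PT lists supplied.
* The dedup rule is deterministic field matching; probabilistic record
  linkage would catch near-duplicates it misses.
* The Wald ROR interval is asymptotic; at very small counts the flag rate
  sits below nominal (conservative), as the type-I simulation shows.
* Therapy episodes are collapsed to earliest start / latest end per drug;
  re-challenge patterns within a report are not modelled.
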