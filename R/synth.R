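# Synthetic spontaneous-report generator with recorded ground truth.
#
# Reports are drawn independently; within a report each SMQ fires as a
# Bernoulli event with probability baseline * (reporting ratio if the report
# belongs to the target-drug stratum).  Therapy-start and event dates are
# generated so that the target stratum's onset delays follow a configurable
# per-SMQ distribution, demographics carry configurable missingness, and
# key-identical duplicates can be injected at a configurable rate.  Output
# is written in the FAERS ASCII dialect so the ingestion path is exercised
# unchanged.

BACKGROUND_PTS <- c(
  "Rash", "Nausea", "Fatigue", "Diarrhoea", "Headache", "Pyrexia",
  "Vomiting", "Dizziness", "Pruritus", "Anaemia", "Cough", "Constipation",
  "Decreased appetite", "Insomnia", "Arthralgia", "Dyspnoea", "Paronychia",
  "Stomatitis", "Oedema peripheral", "Infusion related reaction"
)

BACKGROUND_DRUGS <- c(
  "CARBOPLATIN", "PEMETREXED", "OSIMERTINIB", "PEMBROLIZUMAB", "METFORMIN",
  "ATORVASTATIN", "OMEPRAZOLE", "LEVOTHYROXINE", "AMLODIPINE", "GEFITINIB"
)

default_tto_medians <- function() {
  c(venous_thrombotic_diseases = 94, abnormal_blood_pressure = 33,
    arrhythmia = 8, pericardial_effusion = 60, cardiac_failure = 77,
    stroke = 45, sudden_death = 23, coronary_artery_disease = 570,
    myocardial_injury = 14, peripheral_vascular_disease = 60,
    cardiomyopathy_other = 60)
}

#' Simulator configuration
#'
#' Parameters of the synthetic report generator.  Defaults emulate a
#' desk-scale spontaneous-report cohort: a large background stratum, a
#' target-drug stratum of a few thousand reports, per-SMQ baseline reporting
#' probabilities of the order 0.1-1%, reporting-ratio multipliers elevated
#' for the venous-thrombotic, blood-pressure, arrhythmia and pericardial
#' groupings (the signal pattern a cardiovascular screen is expected to
#' recover), around 40% missing age, Weibull onset-delay distributions with
#' per-SMQ medians from about one week to over a year, and a 5% duplicate
#' rate.
#'
#' @param n_background,n_target stratum sizes (reports).
#' @param baseline_event_prob named probability per SMQ id (background).
#' @param true_rr named positive multiplier per SMQ id applied within the
#'   target stratum; `baseline * rr` must stay at most 1.
#' @param pt_per_smq how many of each SMQ's PTs the generator draws from
#'   (1 concentrates the SMQ's mass on a single PT).
#' @param demographics list: `sex_probs`, `age_mean`, `age_sd`,
#'   `age_missing_rate`, `country_probs`, `occupation_probs`.
#' @param outcome_probs list with per-flag probabilities `death`,
#'   `life_threatening`, `hospitalization`, `disability` for cardiovascular
#'   reports (optionally a named list per SMQ id) and `background` for the
#'   rest.
#' @param tto_dist named list per SMQ id: `list(family, ...)` with family
#'   `"weibull"` (shape, scale), `"lognormal"` (meanlog, sdlog) or
#'   `"fixed"` (value), in days.
#' @param duplicate_rate share of reports duplicated field-identically.
#' @param partial_date_rate share of event dates recorded as partial
#'   (YYYYMM), hence unusable for day-level onset arithmetic.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_background = 100000, n_target = 2000,
                       baseline_event_prob = NULL, true_rr = NULL,
                       pt_per_smq = 3, demographics = list(),
                       outcome_probs = list(), tto_dist = NULL,
                       duplicate_rate = 0.05, partial_date_rate = 0.1,
                       seed = 1L) {
  default_base <- c(
    venous_thrombotic_diseases = 0.004, abnormal_blood_pressure = 0.012,
    arrhythmia = 0.008, pericardial_effusion = 0.0015,
    cardiac_failure = 0.004, stroke = 0.003, sudden_death = 0.001,
    coronary_artery_disease = 0.003, myocardial_injury = 0.001,
    peripheral_vascular_disease = 0.001, cardiomyopathy_other = 0.001)
  default_rr <- c(
    venous_thrombotic_diseases = 12, abnormal_blood_pressure = 1.8,
    arrhythmia = 2.4, pericardial_effusion = 3, cardiac_failure = 1,
    stroke = 1, sudden_death = 1, coronary_artery_disease = 1,
    myocardial_injury = 1, peripheral_vascular_disease = 1,
    cardiomyopathy_other = 1)
  base <- baseline_event_prob %||% default_base
  rr <- true_rr %||% default_rr[names(base)]
  if (is.null(names(base)) || is.null(names(rr)) ||
      !setequal(names(base), names(rr)))
    stopf("baseline_event_prob and true_rr must be named by the same SMQ ids")
  rr <- rr[names(base)]
  if (any(base < 0 | base > 1)) stopf("baseline probabilities must lie in [0,1]")
  if (any(rr <= 0)) stopf("true_rr must be positive")
  if (any(base * rr > 1))
    stopf("infeasible configuration: baseline * rr exceeds 1 for %s",
          paste(names(base)[base * rr > 1], collapse = ", "))
  if (n_background + n_target <= 0) stopf("need at least one report")

  demo_defaults <- list(
    sex_probs = c(F = 0.45, M = 0.35, UNK = 0.20),
    age_mean = 64, age_sd = 11, age_missing_rate = 0.40,
    country_probs = c(US = 0.45, JP = 0.16, CN = 0.05, FR = 0.08, DE = 0.07,
                      GB = 0.05, BR = 0.06, CA = 0.04, AU = 0.02, ZA = 0.02),
    occupation_probs = c(MD = 0.55, PH = 0.30, CN = 0.10, OT = 0.05))
  demographics <- utils::modifyList(demo_defaults, demographics)

  outcome_defaults <- list(
    cardio = c(death = 0.16, life_threatening = 0.16, hospitalization = 0.55,
               disability = 0.02),
    background = c(death = 0.08, life_threatening = 0.05,
                   hospitalization = 0.25, disability = 0.01))
  outcome_probs <- utils::modifyList(outcome_defaults, outcome_probs)

  if (is.null(tto_dist)) {
    med <- default_tto_medians()
    med <- med[names(base)]
    med[is.na(med)] <- 60
    tto_dist <- lapply(med / log(2), function(scale)
      list(family = "weibull", shape = 1, scale = scale))
    names(tto_dist) <- names(base)
  }
  for (s in names(base))
    if (is.null(tto_dist[[s]])) stopf("tto_dist missing for SMQ '%s'", s)

  stopifnot(duplicate_rate >= 0, duplicate_rate <= 1,
            partial_date_rate >= 0, partial_date_rate <= 1)
  structure(list(n_background = n_background, n_target = n_target,
                 baseline_event_prob = base, true_rr = rr,
                 pt_per_smq = pt_per_smq, demographics = demographics,
                 outcome_probs = outcome_probs, tto_dist = tto_dist,
                 duplicate_rate = duplicate_rate,
                 partial_date_rate = partial_date_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

tto_quantile <- function(dist, p) {
  switch(dist$family,
         weibull = stats::qweibull(p, shape = dist$shape, scale = dist$scale),
         lognormal = stats::qlnorm(p, meanlog = dist$meanlog, sdlog = dist$sdlog),
         fixed = rep(dist$value, length(p)),
         stopf("unknown tto family '%s'", dist$family))
}

tto_draw <- function(dist, n) {
  switch(dist$family,
         weibull = stats::rweibull(n, shape = dist$shape, scale = dist$scale),
         lognormal = stats::rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog),
         fixed = rep(dist$value, n),
         stopf("unknown tto family '%s'", dist$family))
}

# True reporting odds ratio implied by the generating probabilities, by the
# odds identity (not the raw rate ratio).
true_ror_from_probs <- function(base, rr) {
  p_t <- base * rr
  (p_t / (1 - p_t)) / (base / (1 - base))
}

#' Generate a synthetic FAERS-style cohort with known ground truth
#'
#' Draws `n_target + n_background` reports under a [sim_config()], writes
#' them into a [raw_quarter()] in the FAERS ASCII dialect, and records the
#' generating truth (true reporting odds ratios by the odds identity, true
#' onset medians, injected duplicate count, latent per-case labels).
#' Reproducible: the same config (including seed) yields identical output.
#'
#' @param config a [sim_config()].
#' @param smq_mapping the PT-to-SMQ mapping the events are drawn from; its
#'   ids must cover the config's SMQ ids.
#' @param quarter_label label for the emitted quarter.
#' @return list with `quarter` (a `raw_quarter`) and `truth` (a
#'   `ground_truth` list).
#' @export
generate_reports <- function(config = sim_config(),
                             smq_mapping = load_smq_mapping(),
                             quarter_label = "2023Q1") {
  stopifnot(inherits(config, "sim_config"))
  missing_smq <- setdiff(names(config$baseline_event_prob), smq_ids(smq_mapping))
  if (length(missing_smq) > 0)
    stopf("config SMQ ids not in the mapping: %s",
          paste(missing_smq, collapse = ", "))
  set.seed(config$seed)
  nt <- config$n_target; nb <- config$n_background; n <- nt + nb
  smqs <- names(config$baseline_event_prob)
  is_target <- c(rep(TRUE, nt), rep(FALSE, nb))
  case_id <- sprintf("%09d", 100000000L + seq_len(n))

  # per-SMQ Bernoulli events
  hit <- matrix(FALSE, nrow = n, ncol = length(smqs),
                dimnames = list(NULL, smqs))
  for (s in smqs) {
    p <- config$baseline_event_prob[[s]] *
      ifelse(is_target, config$true_rr[[s]], 1)
    hit[, s] <- stats::runif(n) < p
  }
  any_hit <- rowSums(hit) > 0
  first_hit <- ifelse(any_hit, smqs[max.col(hit, ties.method = "first")],
                      NA_character_)
  is_cardio <- any_hit

  # demographics
  dg <- config$demographics
  sex <- sample(names(dg$sex_probs), n, replace = TRUE, prob = dg$sex_probs)
  age <- round(pmin(pmax(stats::rnorm(n, dg$age_mean, dg$age_sd), 18), 95))
  age_chr <- as.character(age)
  age_cod <- rep("YR", n)
  age_missing <- stats::runif(n) < dg$age_missing_rate
  age_chr[age_missing] <- ""
  age_cod[age_missing] <- ""
  country <- sample(names(dg$country_probs), n, replace = TRUE,
                    prob = dg$country_probs)
  occp <- sample(names(dg$occupation_probs), n, replace = TRUE,
                 prob = dg$occupation_probs)

  # dates: therapy start uniform over the observation window; event date is
  # start + onset delay (per-SMQ distribution for cardiovascular reports)
  start <- as.Date("2019-01-01") + sample(0:1550, n, replace = TRUE)
  offset <- sample(0:180, n, replace = TRUE)
  for (s in smqs) {
    idx <- which(is_cardio & first_hit == s)
    if (length(idx) > 0)
      offset[idx] <- floor(tto_draw(config$tto_dist[[s]], length(idx)))
  }
  event_date <- start + offset
  end <- start + offset + sample(0:60, n, replace = TRUE)
  event_dt <- format_faers_date(event_date)
  partial <- stats::runif(n) < config$partial_date_rate
  event_dt[partial] <- substr(event_dt[partial], 1L, 6L)
  fda_dt <- format_faers_date(event_date + sample(0:60, n, replace = TRUE))

  # reactions: 1-3 background PTs per report plus one representative PT per
  # SMQ hit (drawn among the SMQ's first pt_per_smq mapping terms)
  n_bg_pt <- 1L + stats::rbinom(n, 2L, 0.3)
  reac_id <- rep(case_id, n_bg_pt)
  reac_pt <- sample(BACKGROUND_PTS, sum(n_bg_pt), replace = TRUE)
  for (s in smqs) {
    idx <- which(hit[, s])
    if (length(idx) == 0) next
    pts <- smq_mapping$pt[smq_mapping$smq_id == s]
    pts <- pts[seq_len(min(config$pt_per_smq, length(pts)))]
    reac_id <- c(reac_id, case_id[idx])
    reac_pt <- c(reac_pt, sample(pts, length(idx), replace = TRUE))
  }

  # drugs & therapy: drug 1 is the stratum-defining suspect with a therapy
  # episode; about half the reports carry one concomitant drug
  drug1 <- ifelse(is_target, "AMIVANTAMAB", sample(BACKGROUND_DRUGS, n, TRUE))
  has_conc <- stats::runif(n) < 0.5
  conc <- sample(BACKGROUND_DRUGS, n, replace = TRUE)
  drug_id <- c(case_id, case_id[has_conc])
  drug_seq <- c(rep("1", n), rep("2", sum(has_conc)))
  drugname <- c(drug1, conc[has_conc])
  role <- c(rep("PS", n), rep("C", sum(has_conc)))
  ther_id <- case_id
  ther_seq <- rep("1", n)
  start_dt <- format_faers_date(start)
  end_dt <- format_faers_date(end)

  # outcomes
  op <- config$outcome_probs
  flag_codes <- c(death = "DE", life_threatening = "LT",
                  hospitalization = "HO", disability = "DS")
  group <- ifelse(is_cardio, first_hit, "background")
  grp_levels <- unique(group)
  grp_probs <- vapply(grp_levels, function(g) {
    p <- if (g == "background") op$background else op[[g]] %||% op$cardio
    p[names(flag_codes)]
  }, numeric(4))
  pm <- t(grp_probs)[match(group, grp_levels), , drop = FALSE]
  colnames(pm) <- names(flag_codes)
  outc_id <- character(0); outc_cod <- character(0)
  for (fl in names(flag_codes)) {
    on <- stats::runif(n) < pm[, fl]
    outc_id <- c(outc_id, case_id[on])
    outc_cod <- c(outc_cod, rep(flag_codes[[fl]], sum(on)))
  }

  demo <- data.frame(primaryid = case_id, event_dt = event_dt, fda_dt = fda_dt,
                     age = age_chr, age_cod = age_cod, sex = sex,
                     occp_cod = occp, reporter_country = country,
                     stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = drug_id, drug_seq = drug_seq,
                     role_cod = role, drugname = drugname,
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = reac_id, pt = reac_pt, stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = outc_id, outc_cod = outc_cod,
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = ther_id, dsg_drug_seq = ther_seq,
                     start_dt = start_dt, end_dt = end_dt,
                     stringsAsFactors = FALSE)

  # inject field-identical duplicates (everything copied except the id)
  n_dup <- floor(config$duplicate_rate * n)
  dup_source <- character(0)
  if (n_dup > 0) {
    src <- sample(case_id, n_dup)
    dup_source <- src
    new_id <- sprintf("%09d", 900000000L + seq_len(n_dup))
    copy_rows <- function(df) {
      idx <- match(df$primaryid, src)
      sel <- !is.na(idx)
      cp <- df[sel, , drop = FALSE]
      cp$primaryid <- new_id[idx[sel]]
      rbind(df, cp)
    }
    demo <- copy_rows(demo); drug <- copy_rows(drug); reac <- copy_rows(reac)
    outc <- copy_rows(outc); ther <- copy_rows(ther)
  }

  truth_memberships <- data.frame(
    case_id = rep(case_id, ncol(hit))[as.vector(hit)],
    smq_id = rep(smqs, each = n)[as.vector(hit)],
    stringsAsFactors = FALSE)
  truth <- structure(list(
    true_ror = true_ror_from_probs(config$baseline_event_prob, config$true_rr),
    true_tto_median = vapply(config$tto_dist, tto_quantile, numeric(1), p = 0.5),
    injected_duplicates = n_dup,
    duplicate_source_ids = dup_source,
    labels = data.frame(case_id = case_id, is_target = is_target,
                        is_cardio = is_cardio, first_smq = first_hit,
                        tto_days = offset, stringsAsFactors = FALSE),
    memberships = truth_memberships,
    config = config), class = "ground_truth")

  list(quarter = raw_quarter(quarter_label, demo, drug, reac, outc, ther),
       truth = truth)
}

#' Inject field-identical duplicate cases
#'
#' Copies `floor(rate * n)` randomly chosen cases under fresh case ids
#' (all other fields identical), so every injected copy collides with its
#' source on the deduplication key and [deduplicate()] removes exactly the
#' injected count when the input was duplicate-free.
#'
#' @param cases a `faers_cases`.
#' @param rate duplication rate in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `cases` (augmented), `injected` (count) and
#'   `injected_ids`.
#' @export
inject_duplicates <- function(cases, rate, seed = 1L) {
  stopifnot(inherits(cases, "faers_cases"), rate >= 0, rate <= 1)
  set.seed(seed)
  n <- n_cases(cases)
  n_dup <- floor(rate * n)
  if (n_dup == 0)
    return(list(cases = cases, injected = 0L, injected_ids = character(0)))
  src <- sample(cases$demo$case_id, n_dup)
  new_id <- sprintf("ZDUP%07d", seq_len(n_dup))
  copy_rows <- function(df) {
    idx <- match(df$case_id, src)
    sel <- !is.na(idx)
    cp <- df[sel, , drop = FALSE]
    cp$case_id <- new_id[idx[sel]]
    out <- rbind(df, cp)
    rownames(out) <- NULL
    out
  }
  out <- new_faers_cases(copy_rows(cases$demo), copy_rows(cases$drugs),
                         copy_rows(cases$reactions), copy_rows(cases$outcomes),
                         log = cases$log)
  out$demo <- out$demo[order(out$demo$case_id), , drop = FALSE]
  rownames(out$demo) <- NULL
  list(cases = out, injected = n_dup, injected_ids = new_id)
}

#' Fast contingency-count simulation under the generative model
#'
#' Draws per-SMQ case/non-case counts directly from the generator's
#' per-report Bernoulli law: within each simulated cohort,
#' `a ~ Binomial(n_target, baseline * rr)` and
#' `c ~ Binomial(n_background, baseline)` with `b`, `d` the stratum
#' remainders.  This is distributionally identical to generating every
#' report and counting in report mode, and makes many-seed operating
#' characteristics (type-I error, power of the signal criterion) cheap to
#' estimate.  ROR/IC statistics and the signal flag are computed for every
#' simulated table.
#'
#' @param n_target,n_background stratum sizes.
#' @param baseline_event_prob named background probability per SMQ.
#' @param true_rr named reporting-ratio multiplier per SMQ.
#' @param n_sims number of simulated cohorts.
#' @param seed RNG seed.
#' @param min_count signal count gate.
#' @param ci_method IC interval method.
#' @return data.frame with one row per (simulation, SMQ): counts,
#'   `ror025`, `ic025`, and `signal`.
#' @export
simulate_screen_counts <- function(n_target, n_background,
                                   baseline_event_prob, true_rr,
                                   n_sims = 500, seed = 1L, min_count = 3,
                                   ci_method = "wald_ic") {
  stopifnot(setequal(names(baseline_event_prob), names(true_rr)))
  set.seed(seed)
  smqs <- names(baseline_event_prob)
  rows <- lapply(smqs, function(s) {
    p_t <- baseline_event_prob[[s]] * true_rr[[s]]
    p_b <- baseline_event_prob[[s]]
    a <- stats::rbinom(n_sims, n_target, p_t)
    c_ <- stats::rbinom(n_sims, n_background, p_b)
    data.frame(sim = seq_len(n_sims), smq_id = s, a = a, b = n_target - a,
               c = c_, d = n_background - c_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  r <- ror_core(out$a, out$b, out$c, out$d)
  ic <- ic_core(out$a, out$b, out$c, out$d, ci_method)
  out$ror <- r$ror; out$ror025 <- r$ror025; out$ror975 <- r$ror975
  out$ic <- ic$ic; out$ic025 <- ic$ic025; out$ic975 <- ic$ic975
  out$signal <- flag_signal(out, min_count = min_count)
  rownames(out) <- NULL
  out
}
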