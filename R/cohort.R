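# Deduplication, target-drug identification, and classification of reaction
# PTs into custom cardiovascular SMQ groupings and analysis cohorts.

#' Default MACE composite
#'
#' SMQ identifiers whose members count as major adverse cardiovascular
#' events (MACE): cardiac failure, stroke, sudden death, coronary artery
#' disease and myocardial injury.  Override per analysis where a different
#' composite is wanted.
#'
#' @return character vector of SMQ identifiers.
#' @export
default_mace_smqs <- function() {
  c("cardiac_failure", "stroke", "sudden_death",
    "coronary_artery_disease", "myocardial_injury")
}

#' Load a PT-to-SMQ mapping
#'
#' Reads a tab-delimited mapping with columns `smq_id`, `smq_name`,
#' `pt_term` (one PT per row; rows sharing an `smq_id` form one grouping).
#' PT matching downstream is case-insensitive.  The shipped default,
#' `smq_cardiovascular_synthetic.tsv`, defines 11 cardiovascular groupings
#' with constructed placeholder PT lists; replace it with a curated mapping
#' for real analyses.
#'
#' @param mapping_file path to the mapping file; `NULL` loads the shipped
#'   default.
#' @return an `smq_mapping` data.frame with columns `smq_id`, `smq_name`,
#'   `pt`, `pt_folded`; attribute `smq_table` lists the definitions and
#'   attribute `overlap_pts` the PTs shared by several SMQs.
#' @export
load_smq_mapping <- function(mapping_file = NULL) {
  if (is.null(mapping_file))
    mapping_file <- system.file("extdata", "smq_cardiovascular_synthetic.tsv",
                                package = "faersignal", mustWork = TRUE)
  df <- utils::read.delim(mapping_file, colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("smq_id", "smq_name", "pt_term")
  if (!all(required %in% names(df)))
    stopf("SMQ mapping must have columns %s", paste(required, collapse = ", "))
  df$smq_id <- trimws(df$smq_id)
  df$smq_name <- trimws(df$smq_name)
  df$pt_term <- trimws(df$pt_term)
  if (any(!nzchar(df$smq_id)))
    stopf("SMQ mapping has rows with empty smq_id")
  names_per_id <- tapply(df$smq_name, df$smq_id,
                         function(v) length(unique(v)))
  if (any(names_per_id > 1))
    stopf("duplicate smq_id with conflicting names: %s",
          paste(names(names_per_id)[names_per_id > 1], collapse = ", "))
  pts_per_id <- tapply(nzchar(df$pt_term), df$smq_id, sum)
  if (any(pts_per_id == 0))
    stopf("SMQ(s) with empty PT set: %s",
          paste(names(pts_per_id)[pts_per_id == 0], collapse = ", "))
  df <- df[nzchar(df$pt_term), , drop = FALSE]
  out <- data.frame(smq_id = df$smq_id, smq_name = df$smq_name,
                    pt = df$pt_term, pt_folded = tolower(df$pt_term),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  smq_table <- unique(out[, c("smq_id", "smq_name")])
  rownames(smq_table) <- NULL
  pairs <- unique(out[, c("smq_id", "pt_folded")])
  dup_pt <- pairs$pt_folded[duplicated(pairs$pt_folded)]
  structure(out, class = c("smq_mapping", "data.frame"),
            smq_table = smq_table,
            overlap_pts = sort(unique(dup_pt)))
}

#' SMQ identifiers declared by a mapping
#' @param mapping an `smq_mapping`.
#' @return character vector of SMQ ids, in mapping order.
#' @export
smq_ids <- function(mapping) attr(mapping, "smq_table")$smq_id

#' Flag cases reporting the target drug
#'
#' A case matches when any of its drugs' normalized names equals, or
#' contains as a whole word, any normalized name in `name_list` (generic
#' plus brand names).  Role codes are not filtered by default; pass
#' `roles = c("PS", "SS")` to restrict to primary/secondary suspects.
#'
#' @param cases a `faers_cases`.
#' @param name_list character vector of drug names (generic and brands).
#' @param roles optional character vector of role codes to restrict to.
#' @return logical vector aligned with `cases$demo` rows, named by case id.
#' @export
match_target_drug <- function(cases, name_list, roles = NULL) {
  stopifnot(inherits(cases, "faers_cases"), length(name_list) > 0)
  drugs <- cases$drugs
  if (!is.null(roles)) drugs <- drugs[drugs$role %in% roles, , drop = FALSE]
  targets <- unique(normalize_drug_name(name_list))
  targets <- targets[!is.na(targets) & nzchar(targets)]
  hit <- rep(FALSE, nrow(drugs))
  for (tg in targets) {
    pattern <- paste0("(^| )", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tg),
                      "( |$)")
    hit <- hit | grepl(pattern, drugs$normalized_name)
  }
  matched_ids <- unique(drugs$case_id[hit])
  out <- cases$demo$case_id %in% matched_ids
  names(out) <- cases$demo$case_id
  out
}

dedup_key <- function(cases) {
  demo <- cases$demo
  ids <- demo$case_id
  age_chr <- ifelse(is.na(demo$age_years), MISSING_TOKEN,
                    sprintf("%.6f", demo$age_years))
  country_chr <- ifelse(is.na(demo$country) | !nzchar(demo$country),
                        MISSING_TOKEN, demo$country)
  pt_set <- collapse_sorted_set(cases$reactions$case_id,
                                tolower(cases$reactions$pt), ids)
  drug_set <- collapse_sorted_set(cases$drugs$case_id,
                                  cases$drugs$normalized_name, ids)
  start_set <- collapse_sorted_set(cases$drugs$case_id,
                                   as.integer(cases$drugs$therapy_start), ids)
  end_set <- collapse_sorted_set(cases$drugs$case_id,
                                 as.integer(cases$drugs$therapy_end), ids)
  paste(demo$sex, age_chr, country_chr, pt_set, drug_set, start_set, end_set,
        sep = "\r")
}

#' Remove duplicate reports
#'
#' Two reports are duplicates when they agree on all seven key components:
#' sex, age in years, reporting country, the sorted set of reaction PTs,
#' the sorted set of normalized drug names, and the sorted sets of therapy
#' start and end dates.  Missing components participate as an explicit
#' missing token, so two reports both missing age can still collide.  One
#' representative per key is kept: the lexicographically greatest case id
#' (FAERS convention, proxy for the latest report version).
#'
#' @param cases a `faers_cases`.
#' @return list with `cases` (the kept `faers_cases`), `removed_count`, and
#'   `removed_ids`.  `removed_count + n_cases(kept) == n_cases(input)`.
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  n <- n_cases(cases)
  if (n == 0)
    return(list(cases = cases, removed_count = 0L, removed_ids = character(0)))
  key <- dedup_key(cases)
  ord <- order(cases$demo$case_id, decreasing = TRUE)
  keep_first <- !duplicated(key[ord])
  kept_ids <- cases$demo$case_id[ord][keep_first]
  removed_ids <- setdiff(cases$demo$case_id, kept_ids)
  kept <- subset_cases(cases, kept_ids)
  list(cases = kept, removed_count = length(removed_ids),
       removed_ids = removed_ids)
}

#' Classify cases into SMQ memberships and analysis cohorts
#'
#' For every case: `smq_memberships` are the SMQs whose PT set intersects
#' the case's reactions (case-insensitive); `is_cardio` means non-empty
#' membership; `is_mace` means membership intersects `mace_smqs`;
#' outcome flags derive from the outcome codes (`DE` death, `LT`
#' life-threatening, `HO` hospitalization, `DS` disability, `CA`
#' congenital anomaly) and `is_serious` means any of the five is present.
#' When `drug_names` is supplied an `is_target` column is added via
#' [match_target_drug()].
#'
#' @param cases a `faers_cases`.
#' @param smq_mapping an `smq_mapping` from [load_smq_mapping()].
#' @param mace_smqs SMQ ids forming the MACE composite (must be declared in
#'   the mapping).
#' @param drug_names optional target drug name list.
#' @param roles optional role restriction passed to [match_target_drug()].
#' @return a `faers_labeled` object: the case set plus `$labels` (one row
#'   per case) and `$memberships` (long case-SMQ pairs).
#' @export
label_cases <- function(cases, smq_mapping = load_smq_mapping(),
                        mace_smqs = default_mace_smqs(),
                        drug_names = NULL, roles = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  declared <- smq_ids(smq_mapping)
  bad <- setdiff(mace_smqs, declared)
  if (length(bad) > 0)
    stopf("mace_smqs not declared in the mapping: %s", paste(bad, collapse = ", "))

  ids <- cases$demo$case_id
  reac <- cases$reactions
  hits <- merge(
    data.frame(case_id = reac$case_id, pt_folded = tolower(reac$pt),
               stringsAsFactors = FALSE),
    smq_mapping[, c("smq_id", "pt_folded")],
    by = "pt_folded"
  )
  memberships <- unique(hits[, c("case_id", "smq_id")])
  memberships <- memberships[order(memberships$case_id, memberships$smq_id), ,
                             drop = FALSE]
  rownames(memberships) <- NULL

  is_cardio <- ids %in% memberships$case_id
  is_mace <- ids %in% memberships$case_id[memberships$smq_id %in% mace_smqs]

  oc <- cases$outcomes
  flag_for <- function(code) ids %in% oc$case_id[oc$outcome == code]
  labels <- data.frame(
    case_id = ids,
    is_cardio = is_cardio,
    is_mace = is_mace,
    death = flag_for("DE"),
    life_threatening = flag_for("LT"),
    hospitalization = flag_for("HO"),
    disability = flag_for("DS"),
    congenital_anomaly = flag_for("CA"),
    has_outcome = ids %in% oc$case_id,
    stringsAsFactors = FALSE
  )
  labels$is_serious <- labels$death | labels$life_threatening |
    labels$hospitalization | labels$disability | labels$congenital_anomaly
  if (!is.null(drug_names))
    labels$is_target <- unname(match_target_drug(cases, drug_names, roles))

  out <- cases
  out$labels <- labels
  out$memberships <- memberships
  out$smq_mapping <- smq_mapping
  out$mace_smqs <- mace_smqs
  class(out) <- c("faers_labeled", "faers_cases")
  out
}

#' @export
print.faers_labeled <- function(x, ...) {
  cat(sprintf("<faers_labeled> %d cases: %d cardiovascular (%d MACE), %d serious\n",
              nrow(x$demo), sum(x$labels$is_cardio), sum(x$labels$is_mace),
              sum(x$labels$is_serious)))
  if (!is.null(x$labels$is_target))
    cat(sprintf("  target drug: %d cases\n", sum(x$labels$is_target)))
  invisible(x)
}
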