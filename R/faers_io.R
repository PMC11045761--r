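# Reading/writing FAERS-dialect "$"-delimited quarterly ASCII tables and
# assembling joined, normalized case reports.

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "ther")

#' Column dialect for FAERS quarterly ASCII files
#'
#' Describes where each field the pipeline needs lives in the quarterly
#' tables.  The default is the post-2014 FAERS ASCII layout (lower-case
#' column names, `primaryid` as the report identifier); supplying a modified
#' mapping adapts the reader to other dialects without touching the parser.
#'
#' @param demo,drug,reac,outc,ther named character vectors mapping the
#'   pipeline's canonical field names to the column names found in the files.
#' @param file_pattern `sprintf` pattern building a file name from the table
#'   prefix (e.g. `"DEMO"`) and the 2-digit year + quarter suffix (`"21Q3"`).
#' @return a `faers_dialect` list.
#' @export
faers_dialect <- function(
    demo = c(case_id = "primaryid", event_dt = "event_dt", fda_dt = "fda_dt",
             age = "age", age_cod = "age_cod", sex = "sex",
             occp_cod = "occp_cod", reporter_country = "reporter_country"),
    drug = c(case_id = "primaryid", drug_seq = "drug_seq",
             role_cod = "role_cod", drugname = "drugname"),
    reac = c(case_id = "primaryid", pt = "pt"),
    outc = c(case_id = "primaryid", outc_cod = "outc_cod"),
    ther = c(case_id = "primaryid", dsg_drug_seq = "dsg_drug_seq",
             start_dt = "start_dt", end_dt = "end_dt"),
    file_pattern = "%s%s.txt") {
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther, file_pattern = file_pattern),
            class = "faers_dialect")
}

quarter_suffix <- function(quarter_label) {
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter_label))
    stopf("quarter label '%s' is not of the form YYYYQn", quarter_label)
  paste0(substr(quarter_label, 3L, 4L), substr(quarter_label, 5L, 6L))
}

faers_file_name <- function(table, quarter_label, dialect) {
  sprintf(dialect$file_pattern, toupper(table), quarter_suffix(quarter_label))
}

read_faers_table <- function(path, table) {
  if (!file.exists(path))
    stopf("FAERS table '%s' not found: expected file '%s'", toupper(table), path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L)
    stopf("malformed header in '%s': file is empty (line 1)", path)
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  if (length(header) == 0L || anyNA(header) || any(!nzchar(trimws(header))))
    stopf("malformed header in '%s' (line 1): empty column name", path)
  k <- length(header)
  body <- lines[-1L]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = k),
                        stringsAsFactors = FALSE)
    names(df) <- header
    return(df)
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens > k))
    stopf("malformed row in '%s' (line %d): %d fields, header has %d",
          path, which(lens > k)[1L] + 1L, max(lens), k)
  # strsplit drops trailing empty fields; pad to header width with NA
  parts <- lapply(parts, function(p) { length(p) <- k; p })
  m <- matrix(unlist(parts, use.names = FALSE), ncol = k, byrow = TRUE)
  m[!is.na(m) & m == ""] <- NA_character_
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read one FAERS quarter
#'
#' Reads the five quarterly tables (DEMO, DRUG, REAC, OUTC, THER) for one
#' quarter from a directory of `$`-delimited ASCII files.  Values are kept
#' verbatim as text; empty fields become `NA`.  A missing file or malformed
#' header/row is a hard error naming the table and line.
#'
#' @param directory_path directory containing the quarter's files.
#' @param quarter_label quarter as `"YYYYQn"`, e.g. `"2021Q3"`.
#' @param dialect a [faers_dialect()].
#' @return a `raw_quarter` object: the label plus one character data.frame
#'   per table.
#' @seealso [write_quarter()], [assemble_cases()]
#' @export
read_quarter <- function(directory_path, quarter_label,
                         dialect = faers_dialect()) {
  tables <- lapply(FAERS_TABLES, function(tb) {
    path <- file.path(directory_path, faers_file_name(tb, quarter_label, dialect))
    read_faers_table(path, tb)
  })
  names(tables) <- FAERS_TABLES
  structure(c(list(quarter_label = quarter_label), tables),
            class = "raw_quarter")
}

#' Construct a raw quarter in memory
#'
#' @param quarter_label quarter as `"YYYYQn"`.
#' @param demo,drug,reac,outc,ther character data.frames (may have 0 rows).
#' @return a `raw_quarter` object.
#' @export
raw_quarter <- function(quarter_label, demo, drug, reac, outc, ther) {
  structure(list(quarter_label = quarter_label,
                 demo = demo, drug = drug, reac = reac,
                 outc = outc, ther = ther),
            class = "raw_quarter")
}

#' @export
print.raw_quarter <- function(x, ...) {
  cat("<raw_quarter>", x$quarter_label, "\n")
  for (tb in FAERS_TABLES)
    cat(sprintf("  %s: %d rows\n", toupper(tb), nrow(x[[tb]])))
  invisible(x)
}

write_faers_table <- function(df, path) {
  cols <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  body <- if (nrow(df) > 0) do.call(paste, c(cols, sep = "$")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "$"), body), con, useBytes = TRUE)
}

#' Write one FAERS quarter
#'
#' Writes a [raw_quarter()] back to the five `$`-delimited files.  `NA`
#' fields are written as empty strings, so `read_quarter()` of the output
#' recovers an equal object (round-trip exact for all populated fields).
#'
#' @param rq a `raw_quarter`.
#' @param directory_path output directory (created if absent).
#' @param dialect a [faers_dialect()].
#' @return invisibly, the vector of files written.
#' @export
write_quarter <- function(rq, directory_path, dialect = faers_dialect()) {
  stopifnot(inherits(rq, "raw_quarter"))
  for (tb in FAERS_TABLES) {
    id_col <- unname(dialect[[tb]][["case_id"]])
    df <- rq[[tb]]
    if (nrow(df) > 0) {
      if (!id_col %in% names(df))
        stopf("table %s lacks report identifier column '%s'", toupper(tb), id_col)
      ids <- df[[id_col]]
      if (anyNA(ids) || any(!nzchar(ids)))
        stopf("table %s has rows without a report identifier", toupper(tb))
    }
  }
  if (!dir.exists(directory_path))
    dir.create(directory_path, recursive = TRUE)
  if (!dir.exists(directory_path))
    stopf("cannot create output directory '%s'", directory_path)
  files <- vapply(FAERS_TABLES, function(tb) {
    path <- file.path(directory_path,
                      faers_file_name(tb, rq$quarter_label, dialect))
    write_faers_table(rq[[tb]], path)
    path
  }, character(1))
  invisible(files)
}

#' Convert raw age value/unit pairs to years
#'
#' FAERS records age as a value plus a unit code.  Conversion factors:
#' `YR` = 1, `DEC` = 10, `MON` = 1/12, `WK` = 7/365.25, `DY` = 1/365.25,
#' `HR` = 1/8766.  Negative values, unknown units, and results outside
#' `[0, 130]` years become missing.
#'
#' @param value numeric vector of age values.
#' @param unit_code character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years (`NA` where not interpretable).
#' @examples
#' normalize_age(c(65, 780, 6.5), c("YR", "MON", "DEC"))
#' @export
normalize_age <- function(value, unit_code) {
  value <- suppressWarnings(as.numeric(value))
  unit_code <- toupper(trimws(as.character(unit_code)))
  if (length(unit_code) == 1L) unit_code <- rep(unit_code, length(value))
  stopifnot(length(unit_code) == length(value))
  factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
               DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factors[unit_code])
  years <- value * f
  years[is.na(value) | is.na(f) | value < 0] <- NA_real_
  years[!is.na(years) & (years < 0 | years > 130)] <- NA_real_
  years
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("UNK", length(x))
  out[!is.na(x) & x %in% c("F", "M")] <- x[!is.na(x) & x %in% c("F", "M")]
  out
}

normalize_occupation <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("UNK", length(x))
  known <- !is.na(x) & nzchar(x)
  out[known] <- "OT"                       # LW, HP, OT and friends collapse
  direct <- known & x %in% c("MD", "PH", "CN")
  out[direct] <- x[direct]
  out
}

normalize_role <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("UNK", length(x))
  ok <- !is.na(x) & x %in% c("PS", "SS", "C", "I")
  out[ok] <- x[ok]
  out
}

pick_columns <- function(df, mapping, table) {
  missing_cols <- setdiff(unname(mapping), names(df))
  if (nrow(df) > 0 && length(missing_cols) > 0)
    stopf("table %s lacks expected column(s): %s", toupper(table),
          paste(missing_cols, collapse = ", "))
  out <- lapply(mapping, function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else character(nrow(df))
  })
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE,
                col.names = names(mapping))
}

new_faers_cases <- function(demo, drugs, reactions, outcomes, log = list()) {
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, log = log),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d cases, %d drug rows, %d reactions, %d outcome rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  invisible(x)
}

#' Number of cases in a case set
#' @param cases a `faers_cases` object.
#' @return integer count of cases.
#' @export
n_cases <- function(cases) nrow(cases$demo)

#' Assemble normalized case reports from a raw quarter
#'
#' Joins the five quarterly tables on the report identifier into one case
#' set: a demographics table (one row per report) plus child tables for
#' drugs, reaction preferred terms (PTs) and outcome codes.  Normalization:
#' sex to `F/M/UNK`; reporter occupation to `MD/PH/CN/OT/UNK`; age to years
#' via [normalize_age()]; country to macro-region; drug names via
#' [normalize_drug_name()]; therapy dates joined from THER by drug sequence
#' (earliest start / latest end per drug).  Partial dates keep their year
#' but no day-level Date.  Reports with no reactions are dropped and
#' counted; child rows whose identifier has no DEMO row are dropped with a
#' warning.  Children are sorted canonically so the result is independent of
#' input row order.
#'
#' @param rq a `raw_quarter` (or a list of them, which are concatenated).
#' @param dialect a [faers_dialect()].
#' @param report_year_source which date anchors the year of report:
#'   `"fda_dt"` (FDA receipt date, default) or `"event_dt"`.
#' @return a `faers_cases` object; `$log` records dropped-row counts.
#' @export
assemble_cases <- function(rq, dialect = faers_dialect(),
                           report_year_source = c("fda_dt", "event_dt")) {
  report_year_source <- match.arg(report_year_source)
  if (!inherits(rq, "raw_quarter") && is.list(rq)) {
    parts <- lapply(rq, assemble_cases, dialect = dialect,
                    report_year_source = report_year_source)
    return(do.call(combine_cases, parts))
  }
  stopifnot(inherits(rq, "raw_quarter"))

  demo <- pick_columns(rq$demo, dialect$demo, "demo")
  drug <- pick_columns(rq$drug, dialect$drug, "drug")
  reac <- pick_columns(rq$reac, dialect$reac, "reac")
  outc <- pick_columns(rq$outc, dialect$outc, "outc")
  ther <- pick_columns(rq$ther, dialect$ther, "ther")

  log <- list(quarter = rq$quarter_label,
              demo_rows = nrow(demo), duplicate_demo_rows = 0L,
              orphan_drug_rows = 0L, orphan_reac_rows = 0L,
              orphan_outc_rows = 0L, orphan_ther_rows = 0L,
              illegal_outcome_rows = 0L, negative_age_rows = 0L,
              no_reaction_reports = 0L)

  dup <- duplicated(demo$case_id)
  log$duplicate_demo_rows <- sum(dup)
  demo <- demo[!dup, , drop = FALSE]
  ids <- demo$case_id

  drop_orphans <- function(child, what) {
    orphan <- !(child$case_id %in% ids)
    n <- sum(orphan)
    if (n > 0)
      warnf("%d %s row(s) reference report identifiers absent from DEMO; dropped",
            n, what)
    list(child = child[!orphan, , drop = FALSE], n = n)
  }
  o <- drop_orphans(drug, "DRUG"); drug <- o$child; log$orphan_drug_rows <- o$n
  o <- drop_orphans(reac, "REAC"); reac <- o$child; log$orphan_reac_rows <- o$n
  o <- drop_orphans(outc, "OUTC"); outc <- o$child; log$orphan_outc_rows <- o$n
  o <- drop_orphans(ther, "THER"); ther <- o$child; log$orphan_ther_rows <- o$n

  # demographics
  age_value <- suppressWarnings(as.numeric(demo$age))
  log$negative_age_rows <- sum(!is.na(age_value) & age_value < 0)
  event <- parse_faers_date(demo$event_dt)
  fda <- parse_faers_date(demo$fda_dt)
  report_year <- if (report_year_source == "fda_dt") fda$year else event$year
  demo_out <- data.frame(
    case_id = demo$case_id,
    sex = normalize_sex(demo$sex),
    age_years = normalize_age(demo$age, demo$age_cod),
    age_value = age_value,
    age_unit = toupper(trimws(as.character(demo$age_cod))),
    occupation = normalize_occupation(demo$occp_cod),
    country = toupper(trimws(as.character(demo$reporter_country))),
    region = map_country_to_region(demo$reporter_country),
    event_date = event$date,
    event_year = event$year,
    report_year = report_year,
    stringsAsFactors = FALSE
  )

  # drugs + therapy dates (earliest start / latest end per drug entry)
  drug_key <- paste(drug$case_id, drug$drug_seq, sep = "\r")
  ts_int <- rep(NA_integer_, nrow(drug))
  te_int <- rep(NA_integer_, nrow(drug))
  if (nrow(ther) > 0) {
    start <- parse_faers_date(ther$start_dt)$date
    end <- parse_faers_date(ther$end_dt)$date
    ther_key <- paste(ther$case_id, ther$dsg_drug_seq, sep = "\r")
    min_start <- suppressWarnings(
      tapply(as.integer(start), ther_key, min, na.rm = TRUE))
    max_end <- suppressWarnings(
      tapply(as.integer(end), ther_key, max, na.rm = TRUE))
    min_start[!is.finite(min_start)] <- NA_integer_
    max_end[!is.finite(max_end)] <- NA_integer_
    ts_int <- as.integer(as.vector(min_start[drug_key]))
    te_int <- as.integer(as.vector(max_end[drug_key]))
  }
  drugs_out <- data.frame(
    case_id = drug$case_id,
    drug_seq = drug$drug_seq,
    verbatim_name = drug$drugname,
    normalized_name = normalize_drug_name(drug$drugname),
    role = normalize_role(drug$role_cod),
    therapy_start = as.Date(ts_int, origin = "1970-01-01"),
    therapy_end = as.Date(te_int, origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  # reactions: keep PT text verbatim, drop empty
  reac_out <- data.frame(case_id = reac$case_id, pt = reac$pt,
                         stringsAsFactors = FALSE)
  reac_out <- reac_out[!is.na(reac_out$pt) & nzchar(trimws(reac_out$pt)), ,
                       drop = FALSE]
  reac_out$pt <- trimws(reac_out$pt)

  # outcomes restricted to the legal code set
  out_code <- toupper(trimws(as.character(outc$outc_cod)))
  legal <- out_code %in% LEGAL_OUTCOME_CODES
  log$illegal_outcome_rows <- sum(!legal & !is.na(out_code) & nzchar(out_code))
  outc_out <- data.frame(case_id = outc$case_id[legal], outcome = out_code[legal],
                         stringsAsFactors = FALSE)
  outc_out <- unique(outc_out)

  # drop reports with zero reactions
  has_reac <- demo_out$case_id %in% reac_out$case_id
  log$no_reaction_reports <- sum(!has_reac)
  demo_out <- demo_out[has_reac, , drop = FALSE]
  keep_ids <- demo_out$case_id
  drugs_out <- drugs_out[drugs_out$case_id %in% keep_ids, , drop = FALSE]
  reac_out <- reac_out[reac_out$case_id %in% keep_ids, , drop = FALSE]
  outc_out <- outc_out[outc_out$case_id %in% keep_ids, , drop = FALSE]

  # canonical order: result independent of input row order
  demo_out <- demo_out[order(demo_out$case_id), , drop = FALSE]
  drugs_out <- drugs_out[order(drugs_out$case_id,
                               suppressWarnings(as.numeric(drugs_out$drug_seq)),
                               drugs_out$drug_seq,
                               drugs_out$normalized_name), , drop = FALSE]
  reac_out <- reac_out[order(reac_out$case_id, reac_out$pt), , drop = FALSE]
  outc_out <- outc_out[order(outc_out$case_id, outc_out$outcome), , drop = FALSE]
  rownames(demo_out) <- rownames(drugs_out) <- rownames(reac_out) <-
    rownames(outc_out) <- NULL

  new_faers_cases(demo_out, drugs_out, reac_out, outc_out, log = list(log))
}

#' Combine several case sets into one
#'
#' @param ... `faers_cases` objects with disjoint case identifiers.
#' @return a single `faers_cases`.
#' @export
combine_cases <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0, all(vapply(parts, inherits, TRUE, "faers_cases")))
  all_ids <- unlist(lapply(parts, function(p) p$demo$case_id))
  if (anyDuplicated(all_ids))
    stopf("cannot combine case sets sharing report identifiers")
  bind <- function(field) {
    do.call(rbind, lapply(parts, `[[`, field))
  }
  demo <- bind("demo"); demo <- demo[order(demo$case_id), , drop = FALSE]
  rownames(demo) <- NULL
  new_faers_cases(demo, bind("drugs"), bind("reactions"), bind("outcomes"),
                  log = do.call(c, lapply(parts, `[[`, "log")))
}

#' Subset a case set by case identifiers
#'
#' @param cases a `faers_cases`.
#' @param ids case identifiers to keep.
#' @return a `faers_cases` restricted to `ids`.
#' @export
subset_cases <- function(cases, ids) {
  stopifnot(inherits(cases, "faers_cases"))
  new_faers_cases(
    cases$demo[cases$demo$case_id %in% ids, , drop = FALSE],
    cases$drugs[cases$drugs$case_id %in% ids, , drop = FALSE],
    cases$reactions[cases$reactions$case_id %in% ids, , drop = FALSE],
    cases$outcomes[cases$outcomes$case_id %in% ids, , drop = FALSE],
    log = cases$log
  )
}
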