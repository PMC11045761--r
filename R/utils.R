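# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Token standing in for a missing value inside deduplication keys, so that
# two reports both missing a field can still collide.
MISSING_TOKEN <- "<MISSING>"

LEGAL_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
SERIOUS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA")

#' Normalize a verbatim drug name
#'
#' Upper-cases, collapses runs of punctuation/whitespace to single spaces and
#' trims, so that brand/generic spellings differing only in case or
#' punctuation compare equal.  Deterministic: the same verbatim string always
#' yields the same normalized string.
#'
#' @param x character vector of verbatim drug names.
#' @return character vector of normalized names (`NA` stays `NA`).
#' @examples
#' normalize_drug_name(c("Rybrevant  350mg", " amivantamab-vmjw"))
#' @export
normalize_drug_name <- function(x) {
  out <- toupper(as.character(x))
  out <- gsub("[^A-Z0-9]+", " ", out)
  out <- trimws(out)
  out[is.na(x)] <- NA_character_
  out
}

# Parse FAERS-style dates: YYYYMMDD gives a full Date; partial YYYYMM / YYYY
# retain only the year (Date is NA so no day-level precision is fabricated).
# Anything else is missing entirely.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !nzchar(x)] <- NA_character_
  date <- rep(as.Date(NA), length(x))
  year <- rep(NA_integer_, length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(full)) date[full] <- as.Date(x[full], format = "%Y%m%d")
  partial <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2})?$", x)
  has_year <- full | partial
  year[has_year] <- as.integer(substr(x[has_year], 1L, 4L))
  # a syntactically full but impossible date (e.g. 20210230) keeps its year
  data.frame(date = date, year = year)
}

format_faers_date <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

# Collapse values into one sorted, deduplicated, "|"-joined string per id.
# Used to build order-insensitive set components of deduplication keys.
collapse_sorted_set <- function(ids, values, universe) {
  values <- as.character(values)
  values[is.na(values)] <- MISSING_TOKEN
  split_vals <- split(values, factor(ids, levels = universe))
  vapply(split_vals, function(v) paste(sort(unique(v)), collapse = "|"), character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
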