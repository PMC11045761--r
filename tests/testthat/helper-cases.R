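# Builders for tiny in-code fixtures: compact per-case specs -> raw FAERS
# tables -> assembled case sets.

`%or%` <- function(x, y) if (is.null(x)) y else x

toy_quarter <- function(cases, label = "2021Q1") {
  demo <- do.call(rbind, lapply(cases, function(cs) data.frame(
    primaryid = cs$id,
    event_dt = cs$event %or% "",
    fda_dt = cs$fda %or% "20210301",
    age = cs$age %or% "",
    age_cod = cs$age_cod %or% (if (is.null(cs$age)) "" else "YR"),
    sex = cs$sex %or% "",
    occp_cod = cs$occp %or% "MD",
    reporter_country = cs$country %or% "US",
    stringsAsFactors = FALSE)))
  drug <- do.call(rbind, lapply(cases, function(cs) {
    drugs <- cs$drugs %or% "AMIVANTAMAB"
    data.frame(primaryid = cs$id, drug_seq = as.character(seq_along(drugs)),
               role_cod = rep(cs$roles %or% "PS", length.out = length(drugs)),
               drugname = drugs, stringsAsFactors = FALSE)
  }))
  ther <- do.call(rbind, lapply(cases, function(cs) {
    drugs <- cs$drugs %or% "AMIVANTAMAB"
    starts <- rep(cs$start %or% "", length.out = length(drugs))
    ends <- rep(cs$end %or% "", length.out = length(drugs))
    data.frame(primaryid = cs$id, dsg_drug_seq = as.character(seq_along(drugs)),
               start_dt = starts, end_dt = ends, stringsAsFactors = FALSE)
  }))
  reac <- do.call(rbind, lapply(cases, function(cs) {
    pts <- cs$pts %or% "Rash"
    data.frame(primaryid = cs$id, pt = pts, stringsAsFactors = FALSE)
  }))
  outc_rows <- lapply(cases, function(cs) {
    oc <- cs$outc %or% character(0)
    if (length(oc) == 0) return(NULL)
    data.frame(primaryid = cs$id, outc_cod = oc, stringsAsFactors = FALSE)
  })
  outc_rows <- Filter(Negate(is.null), outc_rows)
  outc <- if (length(outc_rows) > 0) do.call(rbind, outc_rows) else
    data.frame(primaryid = character(0), outc_cod = character(0),
               stringsAsFactors = FALSE)
  raw_quarter(label, demo, drug, reac, outc, ther)
}

toy_cases <- function(cases, ...) {
  suppressWarnings(assemble_cases(toy_quarter(cases), ...))
}

# Independent brute-force deduplication oracle: pairwise comparison of the
# seven key components, each recomputed from the case set directly.
brute_force_dedup_keys <- function(cases) {
  miss <- function(x) ifelse(is.na(x) | !nzchar(as.character(x)), "<M>",
                             as.character(x))
  vapply(cases$demo$case_id, function(id) {
    d <- cases$demo[cases$demo$case_id == id, ]
    dr <- cases$drugs[cases$drugs$case_id == id, ]
    re <- cases$reactions[cases$reactions$case_id == id, ]
    paste(
      miss(d$sex), miss(d$age_years), miss(d$country),
      paste(sort(unique(tolower(re$pt))), collapse = ";"),
      paste(sort(unique(miss(dr$normalized_name))), collapse = ";"),
      paste(sort(unique(miss(as.integer(dr$therapy_start)))), collapse = ";"),
      paste(sort(unique(miss(as.integer(dr$therapy_end)))), collapse = ";"),
      sep = "##")
  }, character(1))
}
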