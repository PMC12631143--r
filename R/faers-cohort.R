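#' Assemble report cases from the four raw tables
#'
#' Merges the demographic, drug, indication and reaction tables on
#' `primaryid` into one record per report version: demographics plus the
#' set of normalized drug names, indication preferred terms and reaction
#' preferred terms (stored as list-columns). Drug names are normalized
#' through the synonym table during the merge. The result still contains
#' multiple versions of the same case; apply [deduplicate_cases()] next.
#'
#' @param tables Named list from [load_faers_tables()].
#' @param synonyms Synonym table for [normalize_drug_names()].
#' @return data.frame of class `faers_cases` with columns `primary_id`,
#'   `case_id`, `sex`, `age_years`, `country`, `reporter`, `report_year`,
#'   `mtx_dose_mg` and list-columns `drugs`, `indication_pts`,
#'   `reaction_pts`.
#' @export
merge_cases <- function(tables, synonyms = default_synonyms()) {
  demo <- tables$demo
  drug <- tables$drug
  indi <- tables$indi
  reac <- tables$reac
  ids <- demo$primaryid
  norm <- normalize_drug_names(drug$drugname, synonyms)
  drugs_by_id <- split(norm, drug$primaryid)
  indi_by_id <- split(indi$indi_pt, indi$primaryid)
  reac_by_id <- split(reac$pt, reac$primaryid)
  dose_raw <- suppressWarnings(as.numeric(drug$dose_mg))
  mtx_dose <- tapply(ifelse(norm == "methotrexate", dose_raw, NA_real_),
                     drug$primaryid, function(v) {
                       v <- v[!is.na(v)]
                       if (length(v)) v[1] else NA_real_
                     })
  pick <- function(lst, id) {
    x <- lst[[id]]
    if (is.null(x)) character(0) else unique(x)
  }
  cases <- data.frame(
    primary_id = as.numeric(ids),
    case_id = as.numeric(demo$caseid),
    sex = demo$sex,
    age_years = suppressWarnings(as.numeric(demo$age_yr)),
    country = demo$country,
    reporter = demo$reporter,
    report_year = suppressWarnings(as.integer(demo$year)),
    stringsAsFactors = FALSE)
  cases$mtx_dose_mg <- as.numeric(mtx_dose[as.character(ids)])
  cases$drugs <- I(lapply(as.character(ids), pick, lst = drugs_by_id))
  cases$indication_pts <- I(lapply(as.character(ids), pick, lst = indi_by_id))
  cases$reaction_pts <- I(lapply(as.character(ids), pick, lst = reac_by_id))
  class(cases) <- c("faers_cases", "data.frame")
  cases
}

#' Deduplicate case versions
#'
#' FAERS reports are versioned: follow-ups share a case identifier under
#' a new primary identifier, and the highest primary identifier is the
#' current record. Keeps one record per `case_id` (the highest
#' `primary_id`). Idempotent.
#'
#' @param cases A `faers_cases` data.frame.
#' @return The deduplicated `faers_cases` data.frame.
#' @export
deduplicate_cases <- function(cases) {
  ord <- order(cases$case_id, -cases$primary_id)
  cases <- cases[ord, , drop = FALSE]
  out <- cases[!duplicated(cases$case_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict to the renal-impairment cohort
#'
#' Keeps cases whose indication preferred terms intersect the renal
#' high-level-term groupings (renal failure and impairment;
#' complications of renal failure).
#'
#' @param cases A `faers_cases` data.frame.
#' @param renal_pts Nonempty character vector of renal indication PTs.
#' @return The retained subset.
#' @export
filter_renal_cohort <- function(cases, renal_pts = renal_pt_set()) {
  if (length(renal_pts) == 0) {
    stop("`renal_pts` must be nonempty", call. = FALSE)
  }
  keep <- vapply(cases$indication_pts,
                 function(p) any(p %in% renal_pts), logical(1))
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Purge non-adverse-reaction preferred terms
#'
#' Removes reaction PTs belonging to the exclusion classes (product
#' issues, social environment, injuries, poisoning, surgical
#' complications, medical procedures). Cases left without any reaction PT
#' carry no adverse-event information and are dropped; the count of
#' dropped cases is recorded in the `n_dropped_empty` attribute.
#'
#' @param cases A `faers_cases` data.frame.
#' @param excluded_pts Character vector of PTs to purge (may be empty,
#'   in which case this is the identity).
#' @return The cleaned `faers_cases` data.frame.
#' @export
exclude_non_adr_pts <- function(cases, excluded_pts = excluded_pt_set()) {
  cleaned <- lapply(cases$reaction_pts, function(p) setdiff(p, excluded_pts))
  keep <- lengths(cleaned) > 0
  out <- cases[keep, , drop = FALSE]
  out$reaction_pts <- I(cleaned[keep])
  rownames(out) <- NULL
  attr(out, "n_dropped_empty") <- sum(!keep)
  class(out) <- c("faers_cases", "data.frame")
  out
}

#' Full cohort-construction pipeline on a report directory
#'
#' Load, merge, deduplicate, restrict to the renal cohort and purge
#' non-adverse-reaction terms, with per-step record counts recorded in
#' the `attrition` attribute.
#'
#' @param dir Directory with the four FAERS tables.
#' @param synonyms Synonym table.
#' @param renal_pts Renal indication PT set; `NULL` skips the cohort
#'   filter.
#' @param excluded_pts Exclusion PT set.
#' @return A cleaned, deduplicated `faers_cases` data.frame.
#' @export
build_cohort <- function(dir, synonyms = default_synonyms(),
                         renal_pts = renal_pt_set(),
                         excluded_pts = excluded_pt_set()) {
  tabs <- load_faers_tables(dir)
  cases <- merge_cases(tabs, synonyms)
  n0 <- nrow(cases)
  cases <- deduplicate_cases(cases)
  n1 <- nrow(cases)
  if (!is.null(renal_pts)) cases <- filter_renal_cohort(cases, renal_pts)
  n2 <- nrow(cases)
  cases <- exclude_non_adr_pts(cases, excluded_pts)
  attr(cases, "attrition") <- c(merged = n0, deduplicated = n1,
                                renal_cohort = n2, cleaned = nrow(cases))
  cases
}
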