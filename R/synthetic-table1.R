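#' Demographic fixture with the published cohort margins
#'
#' Generates a 2,663-row DEMO-style table whose univariate margins equal
#' the published characteristics of the methotrexate renal-impairment
#' cohort exactly: 1,427 female / 780 male / 456 missing; age bins
#' 198 / 130 / 641 / 1,214 / 480; dose bins 316 (2.5 mg) / 201 (10 mg) /
#' 132 (15 mg) / 142 (20 mg) / 284 other / 1,588 missing; reporter,
#' country and report-year margins likewise. Columns are shuffled
#' independently under the seed, so only the margins (not joint
#' distributions) are meaningful. The published age bins 45--65 and
#' 65--100 overlap at 65; age 65 is assigned to the older bin here.
#'
#' @param seed Integer seed for the within-column shuffles.
#' @return data.frame with 2,663 rows and columns `case_id`, `sex`,
#'   `age_years`, `age_bin`, `mtx_dose_mg`, `dose_bin`, `reporter`,
#'   `country`, `report_year`, `year_bin`.
#' @export
generate_table1_fixture <- function(seed = 1) {
  n <- 2663L
  expand <- function(values, counts) rep(values, counts)
  with_rng(seed, {
    sex <- sample(expand(c("F", "M", "unknown"), c(1427L, 780L, 456L)))
    age_bin <- sample(expand(
      c("0-18", "19-45", "45-65", "65-100", "missing"),
      c(198L, 130L, 641L, 1214L, 480L)))
    age_years <- vapply(age_bin, function(b) switch(
      b,
      "0-18" = sample(0:18, 1),
      "19-45" = sample(19:44, 1),
      "45-65" = sample(45:64, 1),
      "65-100" = sample(65:100, 1),
      "missing" = NA_integer_), integer(1), USE.NAMES = FALSE)
    dose_bin <- sample(expand(
      c("2.5", "10", "15", "20", "other", "missing"),
      c(316L, 201L, 132L, 142L, 284L, 1588L)))
    mtx_dose_mg <- vapply(dose_bin, function(b) switch(
      b,
      "other" = sample(c(5, 7.5, 12.5, 17.5, 25), 1),
      "missing" = NA_real_,
      as.numeric(b)), numeric(1), USE.NAMES = FALSE)
    reporter <- sample(expand(
      c("Physician", "Consumer", "Health professional", "Other reporter",
        "missing"),
      c(1091L, 648L, 636L, 208L, 80L)))
    country <- sample(expand(c("CA", "US", "ES", "other", "missing"),
                             c(995L, 527L, 302L, 796L, 43L)))
    year_bin <- sample(expand(c("2019-2024", "2013-2018", "2004-2012"),
                              c(1732L, 923L, 8L)))
    report_year <- vapply(year_bin, function(b) switch(
      b,
      "2019-2024" = sample(2019:2024, 1),
      "2013-2018" = sample(2013:2018, 1),
      "2004-2012" = sample(2004:2012, 1)), integer(1), USE.NAMES = FALSE)
    data.frame(case_id = seq_len(n), sex = sex,
               age_years = age_years, age_bin = age_bin,
               mtx_dose_mg = mtx_dose_mg, dose_bin = dose_bin,
               reporter = reporter, country = country,
               report_year = report_year, year_bin = year_bin,
               stringsAsFactors = FALSE)
  })
}
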