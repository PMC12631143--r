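#' Bundled vocabulary fixtures
#'
#' The package bundles two small plain-text lookup tables standing in for
#' licensed resources: a drug-name synonym table (variant to generic
#' mapping, replacing NLP-based normalization) and a MedDRA-like
#' preferred-term lookup carrying the system organ class, the two renal
#' high-level-term groupings used to define the renal-impairment cohort,
#' and the non-adverse-reaction exclusion classes. Both are deterministic
#' synthetic stand-ins sufficient for the pipeline and its tests, not the
#' licensed dictionaries.
#'
#' @return `default_synonyms()`: data.frame `variant`, `generic`.
#'   `default_pt_lookup()`: data.frame `pt`, `soc`, `hlt`,
#'   `excluded_class`, `renal_indication`.
#' @export
default_synonyms <- function() {
  utils::read.csv(system.file("extdata", "drug_synonyms.csv",
                              package = "mtxrenal"),
                  stringsAsFactors = FALSE)
}

#' @rdname default_synonyms
#' @export
default_pt_lookup <- function() {
  utils::read.csv(system.file("extdata", "pt_lookup.csv",
                              package = "mtxrenal"),
                  stringsAsFactors = FALSE)
}

#' @rdname default_synonyms
#' @export
renal_pt_set <- function() {
  lk <- default_pt_lookup()
  lk$pt[lk$renal_indication == 1]
}

#' @rdname default_synonyms
#' @export
excluded_pt_set <- function() {
  lk <- default_pt_lookup()
  lk$pt[nzchar(lk$excluded_class)]
}

# Read one "$"-delimited ASCII table. Rows whose field count differs from
# the header are skipped and counted.
read_faers_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("missing FAERS table: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(lines[1])) {
    stop(sprintf("empty FAERS table: %s", path), call. = FALSE)
  }
  fields <- strsplit(lines, "$", fixed = TRUE)
  # strsplit drops trailing empty fields; the true field count is the
  # delimiter count + 1
  nfield <- nchar(lines) - nchar(gsub("$", "", lines, fixed = TRUE)) + 1L
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    c(f, rep("", nfield[i] - length(f)))
  })
  header <- fields[[1L]]
  body <- fields[-1L]
  nf <- nfield[-1L]
  ok <- nf == length(header)
  if (length(body) == 0L) {
    stop(sprintf("FAERS table has a header but no records: %s", path),
         call. = FALSE)
  }
  if (any(!ok)) {
    warning(sprintf("%s: skipped %d malformed line(s)", basename(path),
                    sum(!ok)), call. = FALSE)
  }
  body <- body[ok]
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "n_malformed") <- sum(!ok)
  df
}

#' Load the four spontaneous-report tables
#'
#' Reads `DEMO.txt`, `DRUG.txt`, `INDI.txt` and `REAC.txt` (FAERS ASCII
#' dialect: header row, `$`-delimited fields, one record per line) from a
#' directory. All four share `primaryid` and `caseid` key columns.
#' Malformed lines are skipped with a warning and counted in the
#' `n_malformed` attribute of each table.
#'
#' @param dir Directory containing the four files.
#' @return Named list of data.frames: `demo`, `drug`, `indi`, `reac`.
#' @export
load_faers_tables <- function(dir) {
  files <- c(demo = "DEMO.txt", drug = "DRUG.txt", indi = "INDI.txt",
             reac = "REAC.txt")
  tabs <- lapply(files, function(f) read_faers_file(file.path(dir, f)))
  for (nm in names(tabs)) {
    if (!all(c("primaryid", "caseid") %in% names(tabs[[nm]]))) {
      stop(sprintf("table %s lacks primaryid/caseid key columns", nm),
           call. = FALSE)
    }
  }
  tabs
}

#' Normalize free-text drug names against a synonym table
#'
#' Case-insensitive, whitespace-trimmed lookup of reported drug-name
#' variants (brand names, abbreviations, misspellings) to generic names.
#' Unmatched names pass through unchanged (trimmed) and are counted in
#' the `n_unmatched` attribute.
#'
#' @param raw_names Character vector of reported names.
#' @param synonyms data.frame with columns `variant`, `generic`.
#' @return Character vector of normalized names with attribute
#'   `n_unmatched`.
#' @export
normalize_drug_names <- function(raw_names, synonyms = default_synonyms()) {
  key <- tolower(trimws(raw_names))
  idx <- match(key, tolower(trimws(synonyms$variant)))
  out <- ifelse(is.na(idx), trimws(raw_names), synonyms$generic[idx])
  attr(out, "n_unmatched") <- sum(is.na(idx))
  out
}
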