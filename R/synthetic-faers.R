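#' Plan for a synthetic spontaneous-report corpus
#'
#' Describes a FAERS-like corpus with known ground truth: per-PT baseline
#' reporting probabilities, planted drug--event reporting-rate ratios
#' (ratio 1 = no signal), per-drug exposure probabilities, the fraction
#' of cases carrying a renal-impairment indication, the fraction of cases
#' re-reported as versioned duplicates, and a seed.
#'
#' @param n_cases Number of distinct cases (>= 1).
#' @param background_pt_rates Named vector of baseline per-case reporting
#'   probabilities per reaction PT, all in `[0, 1]`. Defaults to modest
#'   rates over the bundled non-excluded reaction vocabulary.
#' @param planted_effects data.frame with columns `drug`, `pt`, `ratio`
#'   (finite, >= 0) giving reporting-rate multipliers applied when the
#'   case carries the drug; empty by default (pure null corpus).
#' @param drug_probs Named vector of independent per-case exposure
#'   probabilities per generic drug.
#' @param renal_fraction Fraction of cases with a renal indication PT.
#' @param dup_fraction Fraction of cases emitted twice (an earlier report
#'   version under a lower primary id), to exercise deduplication.
#' @param seed Integer seed; generation is deterministic given the plan.
#' @return An object of class `signal_plan`.
#' @export
signal_plan <- function(n_cases,
                        background_pt_rates = default_background_rates(),
                        planted_effects = data.frame(drug = character(0),
                                                     pt = character(0),
                                                     ratio = numeric(0)),
                        drug_probs = c(methotrexate = 0.3, prednisone = 0.25,
                                       adalimumab = 0.15, "folic acid" = 0.2,
                                       ibuprofen = 0.15,
                                       hydroxychloroquine = 0.1),
                        renal_fraction = 0.5,
                        dup_fraction = 0.1,
                        seed = 1) {
  if (n_cases < 1 || n_cases != round(n_cases)) {
    stop("`n_cases` must be a positive integer", call. = FALSE)
  }
  if (length(background_pt_rates) == 0) {
    stop("empty PT vocabulary: `background_pt_rates` must be nonempty",
         call. = FALSE)
  }
  if (any(background_pt_rates < 0) || any(background_pt_rates > 1)) {
    stop("background rates must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(planted_effects) > 0 &&
      (any(!is.finite(planted_effects$ratio)) ||
       any(planted_effects$ratio < 0))) {
    stop("planted rate ratios must be finite and >= 0", call. = FALSE)
  }
  if (renal_fraction < 0 || renal_fraction > 1 ||
      dup_fraction < 0 || dup_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 background_pt_rates = background_pt_rates,
                 planted_effects = planted_effects,
                 drug_probs = drug_probs,
                 renal_fraction = renal_fraction,
                 dup_fraction = dup_fraction,
                 seed = seed),
            class = "signal_plan")
}

#' @rdname signal_plan
#' @export
default_background_rates <- function() {
  lk <- default_pt_lookup()
  pts <- lk$pt[lk$renal_indication == 0 & !nzchar(lk$excluded_class)]
  # deterministic spread of modest baseline rates over the vocabulary
  rates <- rep(c(0.01, 0.02, 0.03, 0.015, 0.025), length.out = length(pts))
  names(rates) <- pts
  rates
}

#' Generate report cases with known ground truth
#'
#' Draws the corpus a [signal_plan()] describes, in the merged
#' `faers_cases` representation (before duplication): demographics,
#' independent drug exposures, a renal or non-renal indication, and
#' reaction PTs drawn per baseline rate multiplied by the planted ratio
#' when the case carries the paired drug. Cases drawing no reaction are
#' assigned one PT sampled proportionally to the baseline rates, since a
#' spontaneous report without any reaction term does not occur.
#'
#' @param plan A [signal_plan()].
#' @return A `faers_cases` data.frame (one row per case, all primary ids
#'   distinct).
#' @export
generate_faers_cases <- function(plan) {
  stopifnot(inherits(plan, "signal_plan"))
  n <- plan$n_cases
  rates <- plan$background_pt_rates
  pts <- names(rates)
  drugs <- names(plan$drug_probs)
  renal_pts <- renal_pt_set()
  other_indis <- c("Rheumatoid arthritis", "Psoriasis", "Crohn's disease")
  with_rng(plan$seed, {
    sex <- sample(c("F", "M", "unknown"), n, TRUE, prob = c(0.5, 0.33, 0.17))
    age <- round(stats::runif(n, 18, 90), 1)
    country <- sample(c("CA", "US", "ES", "DE", "JP"), n, TRUE,
                      prob = c(0.35, 0.25, 0.15, 0.15, 0.1))
    reporter <- sample(c("MD", "CN", "HP", "OT"), n, TRUE,
                       prob = c(0.4, 0.25, 0.25, 0.1))
    year <- sample(2004:2024, n, TRUE)
    exposure <- matrix(stats::runif(n * length(drugs)) <
                         rep(plan$drug_probs, each = n),
                       nrow = n, dimnames = list(NULL, drugs))
    none <- rowSums(exposure) == 0
    if (any(none)) {
      forced <- sample(drugs, sum(none), TRUE,
                       prob = plan$drug_probs / sum(plan$drug_probs))
      exposure[cbind(which(none), match(forced, drugs))] <- TRUE
    }
    renal <- stats::runif(n) < plan$renal_fraction
    indication <- ifelse(renal,
                         sample(renal_pts, n, TRUE),
                         sample(other_indis, n, TRUE))
    prob <- matrix(rep(rates, each = n), nrow = n,
                   dimnames = list(NULL, pts))
    pe <- plan$planted_effects
    if (nrow(pe) > 0) {
      for (j in seq_len(nrow(pe))) {
        if (!pe$pt[j] %in% pts || !pe$drug[j] %in% drugs) next
        on_drug <- exposure[, pe$drug[j]]
        prob[on_drug, pe$pt[j]] <- pmin(prob[on_drug, pe$pt[j]] * pe$ratio[j],
                                        1)
      }
    }
    hits <- matrix(stats::runif(n * length(pts)) < prob, nrow = n,
                   dimnames = list(NULL, pts))
    reaction <- lapply(seq_len(n), function(i) pts[hits[i, ]])
    empty <- lengths(reaction) == 0
    if (any(empty)) {
      fallback <- sample(pts, sum(empty), TRUE, prob = rates / sum(rates))
      reaction[empty] <- as.list(fallback)
    }
    on_mtx <- if ("methotrexate" %in% drugs) exposure[, "methotrexate"] else
      rep(FALSE, n)
    mtx_dose <- ifelse(on_mtx, sample(c(2.5, 7.5, 10, 15, 20), n, TRUE),
                       NA_real_)
    cases <- data.frame(primary_id = seq_len(n) * 100 + 2,
                        case_id = as.numeric(seq_len(n)),
                        sex = sex, age_years = age, country = country,
                        reporter = reporter, report_year = year,
                        stringsAsFactors = FALSE)
    cases$mtx_dose_mg <- mtx_dose
    cases$drugs <- I(lapply(seq_len(n), function(i) drugs[exposure[i, ]]))
    cases$indication_pts <- I(as.list(indication))
    cases$reaction_pts <- I(reaction)
    class(cases) <- c("faers_cases", "data.frame")
    cases
  })
}

#' Write a synthetic corpus as FAERS-dialect ASCII tables
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `INDI.txt` and `REAC.txt`
#' (`$`-delimited, header row, one record per line) for the corpus of a
#' [signal_plan()]. A `dup_fraction` share of cases is additionally
#' written as a stale earlier report version sharing the case id under a
#' strictly lower primary id, so the versioned deduplication rule is
#' exercised. Drug name strings are sampled from the synonym table's
#' variants (brand names, abbreviations, misspellings, stray case and
#' whitespace) so name normalization is exercised too.
#'
#' @param plan A [signal_plan()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the generated ground-truth `faers_cases`
#'   data.frame (deduplicated form).
#' @export
generate_faers_tables <- function(plan, out_dir) {
  stopifnot(inherits(plan, "signal_plan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  cases <- generate_faers_cases(plan)
  syn <- default_synonyms()
  with_rng(plan$seed + 1L, {
    n <- nrow(cases)
    n_dup <- floor(plan$dup_fraction * n)
    dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
    versions <- rbind(
      data.frame(row = seq_len(n), primary_id = cases$primary_id),
      data.frame(row = dup_idx, primary_id = cases$primary_id[dup_idx] - 1))
    vcases <- cases[versions$row, , drop = FALSE]
    vcases$primary_id <- versions$primary_id

    variant_of <- function(generic) {
      cand <- syn$variant[syn$generic == generic]
      if (!length(cand)) return(generic)
      v <- sample(cand, 1)
      style <- sample(3, 1)
      if (style == 1) v <- toupper(v)
      if (style == 2) v <- paste0(" ", v, " ")
      v
    }
    demo <- sprintf("%d$%.0f$%s$%s$%s$%s$%d",
                    vcases$primary_id, vcases$case_id, vcases$sex,
                    ifelse(is.na(vcases$age_years), "",
                           format(vcases$age_years)),
                    vcases$country, vcases$reporter, vcases$report_year)
    drug_rows <- do.call(rbind, lapply(seq_len(nrow(vcases)), function(i) {
      dr <- vcases$drugs[[i]]
      data.frame(primary_id = vcases$primary_id[i],
                 case_id = vcases$case_id[i],
                 drugname = vapply(dr, variant_of, ""),
                 dose_mg = ifelse(dr == "methotrexate" &
                                    !is.na(vcases$mtx_dose_mg[i]),
                                  format(vcases$mtx_dose_mg[i]), ""),
                 stringsAsFactors = FALSE)
    }))
    indi_rows <- data.frame(
      primary_id = rep(vcases$primary_id, lengths(vcases$indication_pts)),
      case_id = rep(vcases$case_id, lengths(vcases$indication_pts)),
      indi_pt = unlist(vcases$indication_pts))
    reac_rows <- data.frame(
      primary_id = rep(vcases$primary_id, lengths(vcases$reaction_pts)),
      case_id = rep(vcases$case_id, lengths(vcases$reaction_pts)),
      pt = unlist(vcases$reaction_pts))

    writeLines(c("primaryid$caseid$sex$age_yr$country$reporter$year", demo),
               file.path(out_dir, "DEMO.txt"))
    writeLines(c("primaryid$caseid$drugname$dose_mg",
                 sprintf("%d$%.0f$%s$%s", drug_rows$primary_id,
                         drug_rows$case_id, drug_rows$drugname,
                         drug_rows$dose_mg)),
               file.path(out_dir, "DRUG.txt"))
    writeLines(c("primaryid$caseid$indi_pt",
                 sprintf("%d$%.0f$%s", indi_rows$primary_id,
                         indi_rows$case_id, indi_rows$indi_pt)),
               file.path(out_dir, "INDI.txt"))
    writeLines(c("primaryid$caseid$pt",
                 sprintf("%d$%.0f$%s", reac_rows$primary_id,
                         reac_rows$case_id, reac_rows$pt)),
               file.path(out_dir, "REAC.txt"))
  })
  invisible(cases)
}
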