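#' Build the drug-by-event 2x2 contingency table
#'
#' Cross-classifies the cohort into the four disproportionality cells:
#' `a` = target drug and target PT, `b` = target drug and other PTs,
#' `c` = other drugs and target PT, `d` = neither. The default counting
#' unit is the case--PT pair (each deduplicated case contributes each of
#' its reaction PTs once), matching report-count framing; `unit =
#' "case"` counts each case once, classified by whether it carries the
#' target PT.
#'
#' @param cases A deduplicated `faers_cases` data.frame.
#' @param drug Normalized generic drug name.
#' @param pt Target reaction preferred term.
#' @param unit `"pair"` (default) or `"case"`.
#' @return A list of class `contingency_table` with integer cells `a`,
#'   `b`, `c`, `d` and `N`; `drug_absent` flags a drug absent from the
#'   corpus.
#' @export
build_contingency <- function(cases, drug, pt, unit = c("pair", "case")) {
  unit <- match.arg(unit)
  has_drug <- vapply(cases$drugs, function(d) drug %in% d, logical(1))
  has_pt <- vapply(cases$reaction_pts, function(p) pt %in% p, logical(1))
  if (unit == "pair") {
    npt <- lengths(cases$reaction_pts)
    a <- sum(has_drug & has_pt)
    c_ <- sum(!has_drug & has_pt)
    b <- sum(npt[has_drug]) - a
    d <- sum(npt[!has_drug]) - c_
  } else {
    a <- sum(has_drug & has_pt)
    b <- sum(has_drug & !has_pt)
    c_ <- sum(!has_drug & has_pt)
    d <- sum(!has_drug & !has_pt)
  }
  contingency_table(a, b, c_, d, drug_absent = !any(has_drug))
}

#' @rdname build_contingency
#' @param a,b,c,d Nonnegative integer cells.
#' @param drug_absent Logical flag.
#' @export
contingency_table <- function(a, b, c, d, drug_absent = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  # store as doubles: cell products overflow 32-bit integers on corpora
  # of realistic size
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- sum(cells)
  if (N < 1) stop("contingency table must contain at least one report",
                  call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, N = N,
                 drug_absent = drug_absent),
            class = "contingency_table")
}

#' Proportional reporting ratio with chi-squared test
#'
#' PRR = (a/(a+b)) / (c/(c+d)) with the Pearson chi-squared statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The signal criterion is
#' a >= 3, PRR >= 2 and chi-squared >= 4. No continuity correction is
#' applied by default (the classic rule predates that convention);
#' `yates = TRUE` gives the corrected variant.
#'
#' @param t A `contingency_table`.
#' @param min_count,prr_min,chi2_min Signal criterion thresholds.
#' @param yates Apply the Yates continuity correction to chi-squared.
#' @return List with `prr`, `chi2`, `flag`, `valid` (FALSE when a margin
#'   is zero and the statistic is undefined).
#' @export
compute_prr <- function(t, min_count = 3, prr_min = 2, chi2_min = 4,
                        yates = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; N <- t$N
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(prr = NA_real_, chi2 = NA_real_, flag = FALSE, valid = FALSE))
  }
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(dev - N / 2, 0)
  chi2 <- N * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(prr = prr, chi2 = chi2,
       flag = (a >= min_count) && (prr >= prr_min) && (chi2 >= chi2_min),
       valid = TRUE)
}

#' Reporting odds ratio with Wald 95 percent confidence interval
#'
#' ROR = ad/bc with the log-scale Wald interval
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero the Haldane--Anscombe correction (+0.5 to every cell) is applied
#' and flagged. The signal criterion is a >= 3 (uncorrected count) and
#' CI lower bound > 1.
#'
#' @param t A `contingency_table`.
#' @param min_count Minimum report count.
#' @param ci_low_min Lower-bound criterion.
#' @return List with `ror`, `ci_low`, `ci_high`, `flag`, `corrected`.
#' @export
compute_ror <- function(t, min_count = 3, ci_low_min = 1) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(ror) + c(-1, 1) * 1.96 * se)
  list(ror = ror, ci_low = ci[1], ci_high = ci[2],
       flag = (t$a >= min_count) && (ci[1] > ci_low_min),
       corrected = corrected)
}

#' Bayesian information component with shrinkage (BCPNN)
#'
#' The information component compares the observed report count with its
#' independence expectation `E = (a+b)(a+c)/N` under 0.5-count
#' shrinkage: `IC = log2((a + 0.5) / (E + 0.5))`. Its lower 95%
#' credibility bound uses the closed-form approximation
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2.0 (a+0.5)^{-3/2}`, which tracks
#' the gamma-posterior quantile. The signal criterion is a >= 3 and
#' IC025 > 0.
#'
#' @param t A `contingency_table`.
#' @param min_count Minimum report count.
#' @param ic025_min Lower-bound criterion.
#' @return List with `ic`, `ic025`, `flag`, `expected`.
#' @export
compute_ic <- function(t, min_count = 3, ic025_min = 0) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a
  E <- (t$a + t$b) * (t$a + t$c) / t$N
  ic <- log2((a + 0.5) / (E + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
  list(ic = ic, ic025 = ic025,
       flag = (a >= min_count) && (ic025 > ic025_min),
       expected = E)
}

#' Three-way disproportionality signal detection
#'
#' Computes PRR, ROR and BCPNN statistics for every reaction preferred
#' term reported at least once with the target drug in the cohort. A PT
#' is a signal only when it satisfies all three criteria (frequency >= 3
#' with PRR >= 2 and chi-squared >= 4; ROR 95% CI lower bound > 1;
#' IC025 > 0). Results are ordered by report count descending, ties by
#' PT name.
#'
#' @param cases A cleaned, deduplicated `faers_cases` data.frame.
#' @param drug Normalized generic drug name of interest.
#' @param pt_lookup PT-to-SOC lookup data.frame (columns `pt`, `soc`).
#' @param unit Counting unit for [build_contingency()].
#' @param thresholds Named list overriding the criterion constants:
#'   `min_count`, `prr_min`, `chi2_min`, `ror_ci_low_min`, `ic025_min`.
#' @return data.frame of class `signal_results` with one row per PT:
#'   counts, statistics, per-method flags and the combined
#'   `flag_signal`.
#' @export
detect_signals <- function(cases, drug, pt_lookup = default_pt_lookup(),
                           unit = "pair", thresholds = list()) {
  th <- utils::modifyList(list(min_count = 3, prr_min = 2, chi2_min = 4,
                               ror_ci_low_min = 1, ic025_min = 0),
                          thresholds)
  has_drug <- vapply(cases$drugs, function(d) drug %in% d, logical(1))
  pts <- sort(unique(unlist(cases$reaction_pts[has_drug])))
  rows <- lapply(pts, function(pt) {
    tab <- build_contingency(cases, drug, pt, unit = unit)
    prr <- compute_prr(tab, th$min_count, th$prr_min, th$chi2_min)
    ror <- compute_ror(tab, th$min_count, th$ror_ci_low_min)
    ic <- compute_ic(tab, th$min_count, th$ic025_min)
    soc <- pt_lookup$soc[match(pt, pt_lookup$pt)]
    data.frame(pt = pt,
               soc = if (is.na(soc)) "Unmapped" else soc,
               a = tab$a,
               prr = prr$prr, chi2 = prr$chi2,
               ror = ror$ror, ror_low = ror$ci_low, ror_high = ror$ci_high,
               ic = ic$ic, ic025 = ic$ic025,
               flag_prr = isTRUE(prr$flag), flag_ror = isTRUE(ror$flag),
               flag_bcpnn = isTRUE(ic$flag),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pt = character(0), soc = character(0), a = integer(0),
                      prr = numeric(0), chi2 = numeric(0), ror = numeric(0),
                      ror_low = numeric(0), ror_high = numeric(0),
                      ic = numeric(0), ic025 = numeric(0),
                      flag_prr = logical(0), flag_ror = logical(0),
                      flag_bcpnn = logical(0))
  }
  out$flag_signal <- out$flag_prr & out$flag_ror & out$flag_bcpnn
  out <- out[order(-out$a, out$pt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_results", "data.frame")
  out
}

#' Aggregate flagged signals by system organ class
#'
#' @param signals A `signal_results` data.frame.
#' @return data.frame with `soc`, `n_signals` and `share` (shares sum to
#'   1 over flagged signals; empty input yields zero rows).
#' @export
aggregate_by_soc <- function(signals) {
  sig <- signals[signals$flag_signal, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(soc = character(0), n_signals = integer(0),
                      share = numeric(0)))
  }
  tab <- table(sig$soc)
  out <- data.frame(soc = names(tab), n_signals = as.integer(tab),
                    share = as.integer(tab) / nrow(sig),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_signals, out$soc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
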