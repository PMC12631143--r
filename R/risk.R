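#' Peak-concentration risk threshold under renal impairment
#'
#' The adverse-reaction risk bound for weekly oral methotrexate scales
#' the 0.16 umol/L first-dose Cmax cutoff established in adults with
#' normal renal function linearly in dose (relative to the 2.3 mg
#' baseline dose `m0`) and linearly in renal function (eGFR relative to a
#' normalization constant):
#' \deqn{C_{max,R,T} = c_0 \times \frac{M}{m_0} \times \frac{eGFR}{eGFR_{norm}}}
#'
#' The default normalization `egfr_norm = 90` is the value that
#' reproduces the published threshold table cell-for-cell (the ratio is 1
#' at eGFR 90); the alternative 106.78 (the healthy reference eGFR) is
#' retained as an option and demonstrably does not reproduce the table.
#'
#' @param dose_mg Regimen dose M, mg (> 0). Vectorized.
#' @param egfr eGFR, mL/min/1.73 m2 (> 0). Vectorized.
#' @param m0_mg Baseline dose, mg (2.3).
#' @param c0 Base Cmax cutoff, umol/L (0.16).
#' @param egfr_norm eGFR normalization constant (90 by default).
#' @param digits If non-NULL, round the result to this many decimals
#'   (table presentation); internal consumers use full precision.
#' @return Threshold Cmax in umol/L.
#' @export
compute_threshold <- function(dose_mg, egfr, m0_mg = 2.3, c0 = 0.16,
                              egfr_norm = 90, digits = NULL) {
  if (any(dose_mg <= 0) || any(egfr <= 0) || m0_mg <= 0 || c0 <= 0 ||
      egfr_norm <= 0) {
    stop("all threshold inputs must be positive", call. = FALSE)
  }
  thr <- c0 * (dose_mg / m0_mg) * (egfr / egfr_norm)
  if (!is.null(digits)) thr <- round_half_up(thr, digits)
  thr
}

#' Stage-anchored eGFR grid of the threshold table
#'
#' The seven eGFR anchors of the published threshold table: each stage's
#' entry eGFR followed by its lower bound (stage 1 contributes only its
#' 90 anchor).
#'
#' @return data.frame with columns `stage`, `egfr`.
#' @export
ckd_stage_anchors <- function() {
  data.frame(stage = c("CKD1", "CKD2", "CKD2", "CKD3a", "CKD3a",
                       "CKD3b", "CKD3b"),
             egfr = c(90, 89, 60, 59, 45, 44, 30))
}

#' Generate the threshold table over label regimens
#'
#' Evaluates [compute_threshold()] on the grid of label doses by
#' stage-anchored eGFR values, rounded to 3 decimals as presented.
#'
#' @param doses Label regimen doses, mg.
#' @param anchors data.frame with columns `stage`, `egfr`.
#' @inheritParams compute_threshold
#' @param digits Decimals for presentation rounding.
#' @return data.frame with `stage`, `egfr` and one `mg_<dose>` column per
#'   dose (threshold Cmax, umol/L).
#' @export
generate_threshold_table <- function(doses = c(7.5, 10, 15, 20),
                                     anchors = ckd_stage_anchors(),
                                     m0_mg = 2.3, c0 = 0.16, egfr_norm = 90,
                                     digits = 3) {
  out <- anchors
  for (d in doses) {
    out[[sprintf("mg_%g", d)]] <- compute_threshold(
      d, anchors$egfr, m0_mg = m0_mg, c0 = c0, egfr_norm = egfr_norm,
      digits = digits)
  }
  out
}

# Stage anchor eGFR used for single-point assessment/optimization.
# "entry": the eGFR at which the stage begins (the first Table row per
# stage); "lower": the stage's worst-case lower bound.
stage_anchor_egfr <- function(stage, anchor = c("entry", "lower")) {
  anchor <- match.arg(anchor)
  entry <- c(CKD1 = 90, CKD2 = 89, CKD3a = 59, CKD3b = 44)
  lower <- c(CKD1 = 90, CKD2 = 60, CKD3a = 45, CKD3b = 30)
  tab <- if (anchor == "entry") entry else lower
  if (!stage %in% names(tab)) stop(sprintf("unknown stage '%s'", stage))
  unname(tab[stage])
}

#' Population-level assessment of a label regimen in a CKD stage
#'
#' Simulates the first weekly administration for `n` virtual individuals
#' of the stage and compares each individual's peak concentration with
#' that individual's own risk threshold (their eGFR inserted into the
#' threshold equation at the regimen dose). The regimen verdict is
#' `"exceeds"` when the exceedance fraction is above `exceed_rule`
#' (default 0.5, i.e. the median individual exceeds).
#'
#' @param params A [pbpk_parameters()] object (calibrated healthy model).
#' @param stage CKD stage label.
#' @param dose_mg Regimen dose, mg.
#' @param n Number of virtual individuals.
#' @param seed Seed for the virtual population.
#' @param exceed_rule Exceedance fraction above which the verdict is
#'   `"exceeds"`.
#' @param m0_mg,c0,egfr_norm Threshold constants, as in
#'   [compute_threshold()].
#' @param dt Simulation grid spacing, h.
#' @return A list of class `regimen_assessment`: `stage`, `dose_mg`,
#'   `threshold_at_anchor`, `cmax_median`, `cmax_q05`, `cmax_q95`,
#'   `exceedance_fraction`, `verdict`, and the per-individual data.frame
#'   `detail`.
#' @export
assess_regimen <- function(params, stage, dose_mg, n = 200, seed = 1,
                           exceed_rule = 0.5,
                           m0_mg = 2.3, c0 = 0.16, egfr_norm = 90,
                           dt = 0.1) {
  pop <- generate_virtual_population(stage, n, seed = seed,
                                     GFR_ref = params$GFR_ref)
  cmax <- vapply(pop, function(ind)
    cmax_single_dose(params, ind, dose_mg, dt = dt, duration_h = 72),
    numeric(1))
  egfr <- vapply(pop, `[[`, 0, "egfr")
  thr <- compute_threshold(dose_mg, egfr, m0_mg, c0, egfr_norm)
  exceed <- cmax > thr
  frac <- mean(exceed)
  structure(list(
    stage = stage, dose_mg = dose_mg,
    threshold_at_anchor = compute_threshold(
      dose_mg, stage_anchor_egfr(stage), m0_mg, c0, egfr_norm),
    cmax_median = stats::median(cmax),
    cmax_q05 = unname(stats::quantile(cmax, 0.05)),
    cmax_q95 = unname(stats::quantile(cmax, 0.95)),
    exceedance_fraction = frac,
    verdict = if (frac > exceed_rule) "exceeds" else "below",
    detail = data.frame(id = seq_along(pop), egfr = egfr, cmax = cmax,
                        threshold = thr, exceeds = exceed)),
    class = "regimen_assessment")
}

#' @export
print.regimen_assessment <- function(x, ...) {
  cat(sprintf(
    "<regimen_assessment> %s, %g mg weekly: Cmax median %.3f (90%% band %.3f-%.3f) umol/L\n",
    x$stage, x$dose_mg, x$cmax_median, x$cmax_q05, x$cmax_q95))
  cat(sprintf("  exceedance %.1f%%; verdict: %s\n",
              100 * x$exceedance_fraction, x$verdict))
  invisible(x)
}

#' Tablet-quantized dose optimization for a CKD stage
#'
#' Finds the largest dose, in decrements of one 2.5 mg tablet from the
#' prescribed label regimen, whose simulated peak concentration at the
#' stage's anchor eGFR stays at or below the risk bound of the prescribed
#' regimen. The bound is fixed by the initial (label) dose: the label
#' regimen defines the tolerated risk, and the administered dose is
#' reduced until exposure falls under it. The anchor is the stage-entry
#' eGFR by default (`"entry"`, the first threshold-table row of the
#' stage); `"lower"` anchors at the stage's lower eGFR bound instead.
#'
#' @param params A [pbpk_parameters()] object.
#' @param stage CKD stage label.
#' @param initial_dose_mg Prescribed label dose (positive multiple of
#'   `step`).
#' @param step Tablet strength, mg (2.5).
#' @param anchor `"entry"` or `"lower"` stage anchor eGFR.
#' @param m0_mg,c0,egfr_norm Threshold constants.
#' @param dt Simulation grid spacing, h.
#' @return A list of class `optimized_regimen`: `stage`,
#'   `initial_dose_mg`, `optimized_dose_mg` (NA if even one tablet
#'   exceeds the bound), `reduction_tablets`, `threshold_umol_L`,
#'   `anchor_egfr`, `cmax_at_optimized`, `failed`.
#' @export
optimize_dose <- function(params, stage, initial_dose_mg, step = 2.5,
                          anchor = c("entry", "lower"),
                          m0_mg = 2.3, c0 = 0.16, egfr_norm = 90,
                          dt = 0.05) {
  anchor <- match.arg(anchor)
  if (abs(initial_dose_mg / step - round(initial_dose_mg / step)) > 1e-9 ||
      initial_dose_mg <= 0) {
    stop("`initial_dose_mg` must be a positive multiple of `step`",
         call. = FALSE)
  }
  egfr <- stage_anchor_egfr(stage, anchor)
  ind <- pbpk_individual(egfr = egfr, stage = stage,
                         GFR_ref = params$GFR_ref)
  thr <- compute_threshold(initial_dose_mg, egfr, m0_mg, c0, egfr_norm)
  candidates <- seq(initial_dose_mg, step, by = -step)
  optimized <- NA_real_
  cmax_opt <- NA_real_
  for (d in candidates) {
    cm <- cmax_single_dose(params, ind, d, dt = dt, duration_h = 72)
    if (cm <= thr) {
      optimized <- d
      cmax_opt <- cm
      break
    }
  }
  failed <- is.na(optimized)
  structure(list(stage = stage, initial_dose_mg = initial_dose_mg,
                 optimized_dose_mg = optimized,
                 reduction_tablets = if (failed) NA_integer_ else
                   as.integer(round((initial_dose_mg - optimized) / step)),
                 threshold_umol_L = thr, anchor_egfr = egfr,
                 cmax_at_optimized = cmax_opt, failed = failed),
            class = "optimized_regimen")
}

#' @export
print.optimized_regimen <- function(x, ...) {
  if (x$failed) {
    cat(sprintf(
      "<optimized_regimen> %s from %g mg: no dose >= one tablet stays below %.3f umol/L at eGFR %g\n",
      x$stage, x$initial_dose_mg, x$threshold_umol_L, x$anchor_egfr))
  } else {
    cat(sprintf(
      "<optimized_regimen> %s: %g mg -> %g mg (-%d tablet%s); Cmax %.3f <= threshold %.3f umol/L at eGFR %g\n",
      x$stage, x$initial_dose_mg, x$optimized_dose_mg, x$reduction_tablets,
      if (x$reduction_tablets == 1) "" else "s",
      x$cmax_at_optimized, x$threshold_umol_L, x$anchor_egfr))
  }
  invisible(x)
}

#' Optimized-regimen table over all stages and label doses
#'
#' @param params A [pbpk_parameters()] object.
#' @param stages CKD stage labels.
#' @param doses Label regimen doses, mg.
#' @param ... Passed to [optimize_dose()].
#' @return data.frame with one row per stage x initial dose.
#' @export
generate_optimization_table <- function(params,
                                        stages = c("CKD2", "CKD3a", "CKD3b"),
                                        doses = c(7.5, 10, 15, 20), ...) {
  rows <- list()
  for (s in stages) for (d in doses) {
    o <- optimize_dose(params, s, d, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      stage = s, initial_dose_mg = d,
      optimized_dose_mg = o$optimized_dose_mg,
      reduction_tablets = o$reduction_tablets,
      threshold_umol_L = o$threshold_umol_L,
      anchor_egfr = o$anchor_egfr)
  }
  do.call(rbind, rows)
}
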