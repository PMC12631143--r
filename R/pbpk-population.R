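#' Generate a virtual CKD population
#'
#' Draws `n` virtual individuals for a CKD stage: eGFR uniform over the
#' stage's bounds (stage 1 is eGFR > 90 and is bounded above by the
#' healthy reference value 106.78), height and weight lognormal around the
#' reference adult (176 cm, 73 kg) with small coefficients of variation,
#' and the transporter ratio formed as eGFR / eGFR_ref.
#'
#' @param stage One of `"CKD1"`, `"CKD2"`, `"CKD3a"`, `"CKD3b"`.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param GFR_ref Reference eGFR for the transporter ratio.
#' @param height_cv,weight_cv Lognormal coefficients of variation of the
#'   morphometrics around the reference individual.
#' @return A list of [pbpk_individual()] objects; also available in
#'   data.frame form via [population_table()].
#' @export
generate_virtual_population <- function(stage, n, seed = 1,
                                        GFR_ref = 106.78,
                                        height_cv = 0.035, weight_cv = 0.12) {
  bounds <- ckd_stage_bounds()
  if (!stage %in% names(bounds)) {
    stop(sprintf("unknown CKD stage '%s' (expected one of %s)", stage,
                 paste(names(bounds), collapse = ", ")), call. = FALSE)
  }
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer")
  b <- bounds[[stage]]
  with_rng(seed, {
    egfr <- stats::runif(n, b[1], b[2])
    height <- 176 * exp(stats::rnorm(n, 0, sqrt(log(1 + height_cv^2))))
    weight <- 73 * exp(stats::rnorm(n, 0, sqrt(log(1 + weight_cv^2))))
    age <- stats::runif(n, 25, 70)
    lapply(seq_len(n), function(i) {
      pbpk_individual(age_years = age[i], height_cm = height[i],
                      weight_kg = weight[i], egfr = egfr[i], stage = stage,
                      GFR_ref = GFR_ref)
    })
  })
}

#' @rdname generate_virtual_population
#' @param population A list of `pbpk_individual` objects.
#' @export
population_table <- function(population) {
  do.call(rbind, lapply(seq_along(population), function(i) {
    ind <- population[[i]]
    data.frame(id = i, egfr = ind$egfr, stage = ind$stage,
               age_years = ind$age_years, height_cm = ind$height_cm,
               weight_kg = ind$weight_kg,
               transporter_ratio = ind$transporter_ratio)
  }))
}
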