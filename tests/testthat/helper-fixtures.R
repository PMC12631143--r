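# Shared in-code fixtures and independent oracles.

# Hand-built report cases: construct a faers_cases data.frame directly.
make_cases <- function(primary_id, case_id, drugs, indication_pts,
                       reaction_pts) {
  n <- length(primary_id)
  df <- data.frame(primary_id = primary_id, case_id = case_id,
                   sex = rep("F", n), age_years = rep(50, n),
                   country = rep("US", n), reporter = rep("MD", n),
                   report_year = rep(2020L, n), stringsAsFactors = FALSE)
  df$mtx_dose_mg <- rep(NA_real_, n)
  df$drugs <- I(drugs)
  df$indication_pts <- I(indication_pts)
  df$reaction_pts <- I(reaction_pts)
  class(df) <- c("faers_cases", "data.frame")
  df
}

# Closed-form oral two-compartment concentration (independent of the ODE
# path): first-order absorption ka with bioavailability F, central
# elimination rate k10 = CL/Vc, distribution k12 = Q/Vc, k21 = Q/Vp.
two_compartment_oral <- function(t, dose_umol, F, ka, Vc, CL, Q, Vp) {
  k10 <- CL / Vc
  k12 <- Q / Vc
  k21 <- Q / Vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  alpha <- (s + sqrt(s^2 - 4 * p)) / 2
  beta <- (s - sqrt(s^2 - 4 * p)) / 2
  A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
  B <- (k21 - beta) / ((ka - beta) * (alpha - beta))
  Ck <- (k21 - ka) / ((alpha - ka) * (beta - ka))
  (F * dose_umol * ka / Vc) *
    (A * exp(-alpha * t) + B * exp(-beta * t) + Ck * exp(-ka * t))
}

# Cheap calibration settings used across recovery experiments.
quick_obs_plan <- function(params, noise_cv, seed,
                           doses = c(7.5, 15),
                           times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                           n_subjects = 3) {
  pk_observation_plan(params, doses_mg = doses, sampling_times_h = times,
                      noise_cv = noise_cv, n_subjects_per_dose = n_subjects,
                      seed = seed)
}
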