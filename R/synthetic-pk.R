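#' Plan for synthetic concentration--time observations
#'
#' Describes a healthy-volunteer observation campaign simulated from
#' known model parameters: the true parameter set, the doses studied,
#' a strictly increasing sampling schedule, multiplicative lognormal
#' residual noise, the number of subjects per dose and a seed.
#'
#' @param true_parameters A [pbpk_parameters()] object.
#' @param doses_mg Positive doses, mg.
#' @param sampling_times_h Strictly increasing nonnegative times, h.
#' @param noise_cv Lognormal residual coefficient of variation (>= 0;
#'   0 returns exact model output).
#' @param n_subjects_per_dose Positive integer.
#' @param seed Integer seed.
#' @param individual The [pbpk_individual()] observed.
#' @return An object of class `pk_observation_plan`.
#' @export
pk_observation_plan <- function(true_parameters,
                                doses_mg = c(7.5, 15),
                                sampling_times_h = c(0.25, 0.5, 1, 1.5, 2, 3,
                                                     4, 6, 8, 12, 24),
                                noise_cv = 0.2,
                                n_subjects_per_dose = 6,
                                seed = 1,
                                individual = reference_individual()) {
  stopifnot(inherits(true_parameters, "pbpk_parameters"))
  if (any(doses_mg <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(diff(sampling_times_h) <= 0) || any(sampling_times_h < 0)) {
    stop("sampling times must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (n_subjects_per_dose < 1 ||
      n_subjects_per_dose != round(n_subjects_per_dose)) {
    stop("`n_subjects_per_dose` must be a positive integer", call. = FALSE)
  }
  structure(list(true_parameters = true_parameters, doses_mg = doses_mg,
                 sampling_times_h = sampling_times_h, noise_cv = noise_cv,
                 n_subjects_per_dose = as.integer(n_subjects_per_dose),
                 seed = seed, individual = individual),
            class = "pk_observation_plan")
}

#' Generate noisy concentration observations from known parameters
#'
#' Simulates the true model at the plan's doses and sampling times, then
#' applies multiplicative lognormal noise with unit median and the
#' plan's coefficient of variation per observation. A zero-noise plan
#' returns the model output exactly.
#'
#' @param plan A [pk_observation_plan()].
#' @return data.frame with columns `subject`, `dose_mg`, `time_h`,
#'   `conc_umol_L`.
#' @export
generate_pk_observations <- function(plan) {
  stopifnot(inherits(plan, "pk_observation_plan"))
  tt <- plan$sampling_times_h
  sims <- lapply(plan$doses_mg, function(d) {
    prof <- simulate_profile(plan$true_parameters, plan$individual,
                             pbpk_regimen(d),
                             dt = min(0.05, min(diff(c(0, tt)))),
                             duration_h = max(tt))
    stats::approx(prof$time_h, prof$conc_umol_L, xout = tt)$y
  })
  sdlog <- sqrt(log(1 + plan$noise_cv^2))
  with_rng(plan$seed, {
    rows <- list()
    subj <- 0L
    for (i in seq_along(plan$doses_mg)) {
      for (s in seq_len(plan$n_subjects_per_dose)) {
        subj <- subj + 1L
        noise <- if (plan$noise_cv > 0) {
          exp(stats::rnorm(length(tt), 0, sdlog))
        } else {
          rep(1, length(tt))
        }
        rows[[subj]] <- data.frame(subject = subj,
                                   dose_mg = plan$doses_mg[i],
                                   time_h = tt,
                                   conc_umol_L = sims[[i]] * noise)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate dose--Cmax pairs from a spline model
#'
#' Draws Cmax observations Normal(spline(dose), `noise_sd`), truncated
#' at zero, over a dose grid; the dataset feeds [fit_rcs()] recovery
#' experiments.
#'
#' @param model An [rcs_model()].
#' @param dose_grid Nonempty vector of positive doses, mg.
#' @param noise_sd Residual standard deviation, umol/L (>= 0).
#' @param n_per_dose Observations per grid dose.
#' @param seed Integer seed.
#' @return data.frame with columns `dose_mg`, `cmax_umol_L`.
#' @export
generate_dose_cmax_pairs <- function(model, dose_grid, noise_sd = 0.01,
                                     n_per_dose = 10, seed = 1) {
  stopifnot(inherits(model, "rcs_model"))
  if (length(dose_grid) == 0) stop("empty dose grid", call. = FALSE)
  if (any(dose_grid <= 0)) stop("doses must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  dose <- rep(dose_grid, each = n_per_dose)
  mu <- evaluate_rcs(model, dose)
  with_rng(seed, {
    y <- mu + if (noise_sd > 0) stats::rnorm(length(dose), 0, noise_sd) else 0
    data.frame(dose_mg = dose, cmax_umol_L = pmax(y, 0))
  })
}
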