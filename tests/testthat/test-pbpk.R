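params <- default_pbpk_parameters()

test_that("parameter validation enforces the baseline clearance shares", {
  sh <- clearance_shares(params)
  expect_gt(sh[["renal_share"]], 0.8)
  expect_gte(sh[["secretion_share"]], 0.6)
  expect_lte(sh[["secretion_share"]], 0.8)
  # secretion share too low (non-renal routes kept small so the renal
  # share check does not trip first)
  expect_error(pbpk_parameters(CL_sec = 4, CL_hep = 0.5, CL_bile = 0.3),
               "secretion share")
  # non-renal routes too large
  expect_error(pbpk_parameters(CL_hep = 5), "renal share")
  expect_error(pbpk_parameters(fu = 1.5), "fu")
})

test_that("renal scaling follows the intact nephron hypothesis", {
  half <- pbpk_individual(egfr = 106.78 / 2)
  cl <- scale_to_ckd(params, half)
  expect_equal(cl$transporter_ratio, 0.5)
  expect_equal(cl$CL_sec_eff, params$CL_sec / 2)
  ref <- scale_to_ckd(params, reference_individual())
  expect_equal(ref$transporter_ratio, 1)
  expect_equal(ref$CL_sec_eff, params$CL_sec)
  # hepatic and biliary routes untouched
  expect_equal(cl$CL_hep, params$CL_hep)
  expect_equal(cl$CL_bile, params$CL_bile)
  # absolute GFR via BSA: reference adult is ~1.89 m2
  expect_equal(bsa_dubois(176, 73), 1.8892, tolerance = 1e-4)
})

test_that("mass balance holds within 0.1 percent over single and repeated dosing", {
  prof1 <- simulate_profile(params, regimen = pbpk_regimen(7.5))
  expect_lt(mass_balance_error(prof1), 1e-3)
  prof3 <- simulate_profile(params, regimen = pbpk_regimen(15, 168, 3),
                            dt = 0.2)
  expect_lt(mass_balance_error(prof3), 1e-3)
})

test_that("exposure is linear in dose to 1e-6 relative", {
  m1 <- profile_metrics(simulate_profile(params, regimen = pbpk_regimen(5)))
  m2 <- profile_metrics(simulate_profile(params, regimen = pbpk_regimen(10)))
  expect_equal(m2[["cmax"]] / m1[["cmax"]], 2, tolerance = 1e-6)
  expect_equal(m2[["auc_last"]] / m1[["auc_last"]], 2, tolerance = 1e-6)
})

test_that("an individual at the reference eGFR reproduces the healthy profile", {
  ind <- pbpk_individual(egfr = 106.78)
  a <- simulate_profile(params, reference_individual(), pbpk_regimen(7.5))
  b <- simulate_profile(params, ind, pbpk_regimen(7.5))
  expect_equal(a$conc_umol_L, b$conc_umol_L, tolerance = 1e-12)
})

test_that("steady-state weekly dosing obeys superposition", {
  single <- simulate_profile(params, regimen = pbpk_regimen(10), dt = 0.1,
                             duration_h = 3 * 168)
  multi <- simulate_profile(params, regimen = pbpk_regimen(10, 168, 3),
                            dt = 0.1)
  t <- multi$time_h
  approx_at <- function(prof, tt) {
    out <- rep(0, length(tt))
    ok <- tt >= 0
    out[ok] <- approx(prof$time_h, prof$conc_umol_L, xout = tt[ok],
                      rule = 2)$y
    out
  }
  super <- approx_at(single, t) + approx_at(single, t - 168) +
    approx_at(single, t - 336)
  expect_equal(multi$conc_umol_L, super, tolerance = 1e-4)
})

test_that("peak concentration rises monotonically as renal function falls", {
  egfr_grid <- seq(30, 106.78, length.out = 8)
  cmax <- vapply(egfr_grid, function(e)
    cmax_single_dose(params, pbpk_individual(egfr = e), 15, dt = 0.1,
                     duration_h = 48), numeric(1))
  expect_true(all(diff(cmax) < 0))
})

test_that("filtration-only limit matches the closed-form two-compartment solution", {
  p <- params
  p$fu <- 1
  p$CL_sec <- 1e-9
  p$CL_hep <- 1e-9
  p$CL_bile <- 1e-9
  class(p) <- "pbpk_parameters"
  ind <- reference_individual()
  cl <- scale_to_ckd(p, ind)
  expect_equal(cl$CL_ren, cl$gfr_abs, tolerance = 1e-6)
  prof <- simulate_profile(p, ind, pbpk_regimen(7.5), dt = 0.1,
                           duration_h = 96)
  dose_umol <- 7.5 / p$molecular_weight * 1000
  expected <- two_compartment_oral(prof$time_h, dose_umol, p$F, p$ka,
                                   p$Vc, cl$CL_total, p$Q, p$Vp)
  sel <- prof$time_h >= 0.5
  expect_equal(prof$conc_umol_L[sel], expected[sel], tolerance = 1e-3)
  # terminal slope within 1 percent of the analytic beta phase
  late <- prof$time_h >= 48
  slope <- coef(lm(log(prof$conc_umol_L[late]) ~ prof$time_h[late]))[2]
  k10 <- cl$CL_total / p$Vc
  k12 <- p$Q / p$Vc
  k21 <- p$Q / p$Vp
  s <- k10 + k12 + k21
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  expect_equal(unname(slope), -beta, tolerance = 0.01)
})

test_that("virtual populations respect stage bounds and uniform sampling", {
  pop <- generate_virtual_population("CKD3b", 500, seed = 8)
  egfr <- vapply(pop, `[[`, 0, "egfr")
  expect_true(all(egfr >= 30 & egfr <= 44))
  mid <- (30 + 44) / 2
  se <- (44 - 30) / sqrt(12) / sqrt(500)
  expect_lt(abs(mean(egfr) - mid), 3 * se)
  # deterministic under seed, single individual allowed
  one_a <- generate_virtual_population("CKD2", 1, seed = 4)
  one_b <- generate_virtual_population("CKD2", 1, seed = 4)
  expect_equal(one_a[[1]]$egfr, one_b[[1]]$egfr)
  expect_error(generate_virtual_population("CKD5", 10), "unknown CKD stage")
  tab <- population_table(pop)
  expect_equal(nrow(tab), 500L)
  expect_equal(tab$transporter_ratio, egfr / 106.78)
})

test_that("exposure elasticities follow the linear-model identities", {
  sens <- sensitivity_analysis(params, regimen = pbpk_regimen(7.5),
                               rel_step = 0.02)
  el <- function(nm, col) sens[[col]][sens$parameter == nm]
  expect_equal(el("F", "auc_elasticity"), 1, tolerance = 1e-3)
  # fu enters only through filtration, so the clearance-route elasticities
  # of AUC sum to -1
  cl_sum <- el("fu", "auc_elasticity") + el("CL_sec", "auc_elasticity") +
    el("CL_hep", "auc_elasticity") + el("CL_bile", "auc_elasticity")
  expect_equal(cl_sum, -1, tolerance = 1e-2)
  expect_lt(abs(el("Vc", "auc_elasticity")), 0.02)
  expect_error(sensitivity_analysis(params, rel_step = 0.8), "rel_step")
})

test_that("calibration recovers generating parameters from clean data", {
  plan <- quick_obs_plan(params, noise_cv = 0, seed = 1, n_subjects = 1)
  obs <- generate_pk_observations(plan)
  start <- params
  start$ka <- params$ka * 1.6
  start$Vc <- params$Vc * 0.7
  start$CL_sec <- params$CL_sec * 0.82
  class(start) <- "pbpk_parameters"
  cal <- calibrate_healthy(start, obs, n_starts = 2, seed = 2, maxit = 60)
  expect_lt(abs(cal$params$CL_sec / params$CL_sec - 1), 0.05)
  expect_lt(abs(cal$params$ka / params$ka - 1), 0.05)
  expect_lt(abs(cal$params$Vc / params$Vc - 1), 0.05)
  expect_lt(cal$objective, 1e-4)
})

test_that("calibration tolerates residual noise across seeds", {
  ok <- vapply(1:5, function(s) {
    plan <- quick_obs_plan(params, noise_cv = 0.2, seed = 100 + s,
                           n_subjects = 4)
    obs <- generate_pk_observations(plan)
    start <- params
    start$CL_sec <- params$CL_sec * 1.2
    class(start) <- "pbpk_parameters"
    cal <- calibrate_healthy(start, obs, n_starts = 2, seed = s, maxit = 50)
    abs(cal$params$CL_sec / params$CL_sec - 1) < 0.15
  }, logical(1))
  expect_true(all(ok))
})

test_that("bounds excluding the truth leave the fit on the box edge", {
  plan <- quick_obs_plan(params, noise_cv = 0, seed = 3, n_subjects = 1)
  obs <- generate_pk_observations(plan)
  bounds <- list(ka = c(0.2, 1.0))  # truth is 2.0
  cal <- calibrate_healthy(params, obs, fit_params = "ka", bounds = bounds,
                           n_starts = 2, seed = 4, maxit = 40)
  expect_true(cal$bound_active[["ka"]])
  expect_equal(cal$params$ka, 1.0, tolerance = 1e-3)
})

test_that("evaluation metrics satisfy their defining identities", {
  expect_equal(evaluate_model(c(1, 2, 3), c(1, 2, 3))$mrd, 1)
  expect_equal(evaluate_model(10, 1)$mrd, 10)
  ev <- evaluate_model(c(1, 1), c(1, 1), pred_pk = c(2, 0.5),
                       obs_pk = c(1, 1))
  expect_equal(ev$gmfe_abs, 2)
  expect_equal(ev$gmfr_signed, 1)
  # nonpositive pairs are dropped and counted
  drop <- evaluate_model(c(1, 0, 2), c(1, 1, 2))
  expect_equal(drop$n_dropped, 1L)
  expect_equal(drop$m, 2L)
  # fold fractions
  gof <- evaluate_model(c(1, 1.2, 3), c(1, 1, 1))
  expect_equal(gof$frac_within_2fold, 2 / 3)
  expect_equal(gof$frac_within_1.25fold, 2 / 3)
  # printed variant omits the square root
  pr <- evaluate_model(10, 1, mrd_variant = "printed")
  expect_equal(pr$mrd, 10)
  pr2 <- evaluate_model(c(10, 10), c(1, 1), mrd_variant = "printed")
  expect_equal(pr2$mrd, 10)
  expect_equal(evaluate_model(c(10, 1), c(1, 1))$mrd,
               10^sqrt(0.5), tolerance = 1e-12)
})

test_that("parameter files round-trip through flat text", {
  path <- withr::local_tempfile()
  write_pbpk_parameters(params, path)
  back <- read_pbpk_parameters(path)
  for (nm in c("ka", "F", "Vc", "Vp", "Q", "CL_sec", "CL_hep", "CL_bile",
               "fu", "GFR_ref")) {
    expect_equal(back[[nm]], params[[nm]], tolerance = 1e-10)
  }
  expect_error(read_pbpk_parameters(file.path(tempdir(), "nope.txt")),
               "not found")
})
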