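test_that("plan validation rejects out-of-range inputs", {
  expect_error(signal_plan(0), "positive integer")
  expect_error(signal_plan(10, background_pt_rates = c(A = 1.2)), "\\[0, 1\\]")
  expect_error(signal_plan(10, background_pt_rates = numeric(0)), "empty PT")
  expect_error(signal_plan(10, planted_effects = data.frame(
    drug = "methotrexate", pt = "Nausea", ratio = -1)), "finite")
  expect_error(signal_plan(10, renal_fraction = 1.2), "fractions")
  expect_error(pk_observation_plan(default_pbpk_parameters(),
                                   sampling_times_h = c(1, 1, 2)),
               "strictly increasing")
  expect_error(pk_observation_plan(default_pbpk_parameters(),
                                   noise_cv = -0.1), "noise_cv")
})

test_that("report-table generation is byte-identical under a fixed plan", {
  plan <- signal_plan(n_cases = 150, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_faers_tables(plan, d1)
  generate_faers_tables(plan, d2)
  for (f in c("DEMO.txt", "DRUG.txt", "INDI.txt", "REAC.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("a single-case plan without duplicates emits one record per file", {
  plan <- signal_plan(n_cases = 1, dup_fraction = 0, seed = 1)
  td <- withr::local_tempdir()
  generate_faers_tables(plan, td)
  demo <- readLines(file.path(td, "DEMO.txt"))
  expect_equal(length(demo), 2L)  # header + one case
  indi <- readLines(file.path(td, "INDI.txt"))
  expect_equal(length(indi), 2L)
  reac <- readLines(file.path(td, "REAC.txt"))
  expect_gte(length(reac), 2L)
})

test_that("duplicate versions share the case id under a lower primary id", {
  plan <- signal_plan(n_cases = 100, dup_fraction = 0.2, seed = 6)
  td <- withr::local_tempdir()
  generate_faers_tables(plan, td)
  tabs <- load_faers_tables(td)
  demo <- tabs$demo
  expect_equal(nrow(demo), 120L)
  dups <- demo$caseid[duplicated(demo$caseid)]
  expect_equal(length(dups), 20L)
  for (cid in dups[1:5]) {
    pids <- as.numeric(demo$primaryid[demo$caseid == cid])
    expect_equal(length(pids), 2L)
    expect_true(max(pids) > min(pids))
  }
  # deduplication restores one row per case with the current version
  cases <- deduplicate_cases(merge_cases(tabs))
  expect_equal(nrow(cases), 100L)
  expect_true(all(cases$primary_id %% 100 == 2))
})

test_that("zero-noise observations reproduce the simulated curve exactly", {
  params <- default_pbpk_parameters()
  plan <- pk_observation_plan(params, doses_mg = c(7.5, 15),
                              sampling_times_h = c(0.5, 1, 2, 4, 8),
                              noise_cv = 0, n_subjects_per_dose = 2,
                              seed = 9)
  obs <- generate_pk_observations(plan)
  prof <- simulate_profile(params, regimen = pbpk_regimen(7.5),
                           dt = 0.05, duration_h = 8)
  expected <- approx(prof$time_h, prof$conc_umol_L,
                     xout = c(0.5, 1, 2, 4, 8))$y
  got <- obs$conc_umol_L[obs$subject == 1]
  expect_equal(got, expected, tolerance = 1e-10)
  # subjects at the same dose are identical when noiseless
  expect_equal(obs$conc_umol_L[obs$subject == 1],
               obs$conc_umol_L[obs$subject == 2])
})

test_that("per-dose peak concentrations scale linearly across generated doses", {
  params <- default_pbpk_parameters()
  plan <- pk_observation_plan(params, doses_mg = c(2.5, 7.5, 15),
                              sampling_times_h = seq(0.25, 24, by = 0.25),
                              noise_cv = 0, n_subjects_per_dose = 1, seed = 2)
  obs <- generate_pk_observations(plan)
  cmax <- tapply(obs$conc_umol_L, obs$dose_mg, max)
  expect_equal(unname(cmax[["7.5"]] / cmax[["2.5"]]), 3, tolerance = 1e-3)
  expect_equal(unname(cmax[["15"]] / cmax[["2.5"]]), 6, tolerance = 1e-3)
})

test_that("dose-Cmax pairs fall on the curve at zero noise and truncate at zero", {
  m <- published_rcs_model()
  exact <- generate_dose_cmax_pairs(m, c(2.5, 10, 20), noise_sd = 0,
                                    n_per_dose = 3, seed = 1)
  expect_equal(exact$cmax_umol_L, evaluate_rcs(m, exact$dose_mg))
  noisy <- generate_dose_cmax_pairs(m, c(2.5, 5), noise_sd = 0.5,
                                    n_per_dose = 200, seed = 1)
  expect_true(all(noisy$cmax_umol_L >= 0))
  expect_true(any(noisy$cmax_umol_L == 0))  # truncation actually bites
  expect_error(generate_dose_cmax_pairs(m, numeric(0)), "empty dose grid")
})

test_that("the demographic fixture reproduces every published margin", {
  t1 <- generate_table1_fixture(seed = 2)
  expect_equal(nrow(t1), 2663L)
  expect_equal(as.integer(table(t1$sex)[c("F", "M", "unknown")]),
               c(1427L, 780L, 456L))
  expect_equal(as.integer(table(t1$age_bin)[c("0-18", "19-45", "45-65",
                                          "65-100", "missing")]),
               c(198L, 130L, 641L, 1214L, 480L))
  expect_equal(as.integer(table(t1$dose_bin)[c("2.5", "10", "15", "20",
                                           "other", "missing")]),
               c(316L, 201L, 132L, 142L, 284L, 1588L))
  expect_equal(as.integer(table(t1$reporter)[c("Physician", "Consumer",
                                           "Health professional",
                                           "Other reporter", "missing")]),
               c(1091L, 648L, 636L, 208L, 80L))
  expect_equal(as.integer(table(t1$country)[c("CA", "US", "ES", "other",
                                          "missing")]),
               c(995L, 527L, 302L, 796L, 43L))
  expect_equal(as.integer(table(t1$year_bin)[c("2019-2024", "2013-2018",
                                           "2004-2012")]),
               c(1732L, 923L, 8L))
  # numeric columns agree with their bins
  expect_true(all(t1$age_years[t1$age_bin == "65-100"] >= 65, na.rm = TRUE))
  expect_true(all(t1$report_year[t1$year_bin == "2004-2012"] %in% 2004:2012))
})
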