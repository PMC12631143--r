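#' Pipeline configuration
#'
#' One structured home for every constant the end-to-end run uses, each
#' defaulting to its published value: the three-way signal criterion
#' thresholds, the dose--Cmax spline coefficients and knots, the risk
#' constants (base cutoff 0.16 umol/L, baseline dose 2.3 mg, eGFR
#' normalization 90), the label regimens, the model parameter set, and
#' the synthetic corpus / population sizes used for a run.
#'
#' @param seed Master seed for the run.
#' @param drug Drug of interest (normalized generic name).
#' @param signal_thresholds Named list: `min_count`, `prr_min`,
#'   `chi2_min`, `ror_ci_low_min`, `ic025_min`.
#' @param rcs The published [rcs_model()] used to synthesize dose--Cmax
#'   data.
#' @param risk Named list: `c0`, `m0_mg`, `egfr_norm`.
#' @param regimens Label regimen doses, mg.
#' @param pbpk A [pbpk_parameters()] object (starting values; the run
#'   calibrates from these).
#' @param n_cases Synthetic corpus size.
#' @param planted_effects Planted drug--event rate ratios for the corpus.
#' @param n_population Virtual individuals per stage for assessments.
#' @param calibrate Logical: refit the model to synthetic healthy
#'   observations during the run (`FALSE` uses `pbpk` as-is).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            drug = "methotrexate",
                            signal_thresholds = list(min_count = 3,
                                                     prr_min = 2,
                                                     chi2_min = 4,
                                                     ror_ci_low_min = 1,
                                                     ic025_min = 0),
                            rcs = published_rcs_model(),
                            risk = list(c0 = 0.16, m0_mg = 2.3,
                                        egfr_norm = 90),
                            regimens = c(7.5, 10, 15, 20),
                            pbpk = default_pbpk_parameters(),
                            n_cases = 4000,
                            planted_effects = data.frame(
                              drug = "methotrexate",
                              pt = c("Thrombocytopenia",
                                     "Transaminases increased",
                                     "Pulmonary toxicity"),
                              ratio = c(8, 6, 5)),
                            n_population = 50,
                            calibrate = TRUE) {
  structure(list(seed = seed, drug = drug,
                 signal_thresholds = signal_thresholds, rcs = rcs,
                 risk = risk, regimens = regimens, pbpk = pbpk,
                 n_cases = n_cases, planted_effects = planted_effects,
                 n_population = n_population, calibrate = calibrate),
            class = "pipeline_config")
}

#' Run the full assessment pipeline
#'
#' Executes the stages in order -- synthesize the report corpus, detect
#' signals, fit the dose--Cmax spline, calibrate the concentration
#' model, regenerate the threshold table, assess and optimize the label
#' regimens per CKD stage -- writing every artifact under `out_dir` and
#' a manifest with per-file checksums. Reruns with the same
#' configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; existing artifacts
#'   overwritten).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  artifacts <- character(0)
  keep <- function(...) {
    artifacts <<- c(artifacts, file.path(out_dir, c(...)))
  }
  write_df <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    keep(name)
  }

  # 1. synthetic report corpus
  stage("synth-faers", {
    plan <- signal_plan(n_cases = config$n_cases,
                        planted_effects = config$planted_effects,
                        seed = config$seed)
    generate_faers_tables(plan, file.path(out_dir, "faers"))
    keep(file.path("faers", c("DEMO.txt", "DRUG.txt", "INDI.txt",
                              "REAC.txt")))
  })

  # 2. cohort + signal detection
  signals <- stage("signals", {
    cohort <- build_cohort(file.path(out_dir, "faers"))
    sg <- detect_signals(cohort, config$drug,
                         thresholds = config$signal_thresholds)
    write_df(sg, "signals.csv")
    write_df(aggregate_by_soc(sg), "soc_summary.csv")
    sg
  })

  # 3. dose--Cmax spline refit on synthetic pairs
  stage("fit-rcs", {
    pairs <- generate_dose_cmax_pairs(config$rcs,
                                      dose_grid = seq(2.5, 25, by = 2.5),
                                      noise_sd = 0.01, n_per_dose = 20,
                                      seed = config$seed + 10)
    write_df(pairs, "dose_cmax.csv")
    fit <- fit_rcs(pairs, knots = config$rcs$knots,
                   scaling = config$rcs$scaling)
    write_rcs_model(fit$model, file.path(out_dir, "rcs_model.txt"))
    keep("rcs_model.txt")
  })

  # 4. concentration model calibration on synthetic healthy observations
  params <- stage("pbpk-calibrate", {
    p <- config$pbpk
    if (config$calibrate) {
      obs_plan <- pk_observation_plan(p, noise_cv = 0.15,
                                      n_subjects_per_dose = 4,
                                      seed = config$seed + 20)
      obs <- generate_pk_observations(obs_plan)
      write_df(obs, "pk_observations.csv")
      cal <- calibrate_healthy(p, obs, n_starts = 2, seed = config$seed + 21,
                               maxit = 40)
      p <- cal$params
    }
    write_pbpk_parameters(p, file.path(out_dir, "pbpk_params.txt"))
    keep("pbpk_params.txt")
    anchor <- cmax_single_dose(p, dose_mg = config$risk$m0_mg)
    writeLines(sprintf("cmax_anchor_umol_L = %.6f", anchor),
               file.path(out_dir, "calibration_anchor.txt"))
    keep("calibration_anchor.txt")
    p
  })

  # 5. threshold table
  stage("thresholds", {
    tab2 <- generate_threshold_table(doses = config$regimens,
                                     m0_mg = config$risk$m0_mg,
                                     c0 = config$risk$c0,
                                     egfr_norm = config$risk$egfr_norm)
    write_df(tab2, "table2.csv")
  })

  # 6. regimen assessment + optimization, demographic fixture
  stage("optimize", {
    assessments <- lapply(names(ckd_stage_bounds()), function(s) {
      lapply(config$regimens, function(d) {
        a <- assess_regimen(params, s, d, n = config$n_population,
                            seed = config$seed + 30,
                            m0_mg = config$risk$m0_mg, c0 = config$risk$c0,
                            egfr_norm = config$risk$egfr_norm)
        a$detail <- NULL
        a
      })
    })
    jl <- vapply(unlist(assessments, recursive = FALSE), function(a)
      jsonlite::toJSON(unclass(a), auto_unbox = TRUE, digits = NA),
      character(1))
    writeLines(jl, file.path(out_dir, "assessments.jsonl"))
    keep("assessments.jsonl")
    tab3 <- generate_optimization_table(params, doses = config$regimens,
                                        m0_mg = config$risk$m0_mg,
                                        c0 = config$risk$c0,
                                        egfr_norm = config$risk$egfr_norm)
    write_df(tab3, "table3.csv")
    write_df(generate_table1_fixture(seed = config$seed), "table1.csv")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtxrenal")),
    seed = config$seed,
    drug = config$drug,
    artifacts = lapply(artifacts, function(f) {
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Assemble the report bundle of a completed run
#'
#' Verifies the run directory is complete and writes a short markdown
#' summary next to the CSV artifacts (`table1.csv`, `table2.csv`,
#' `table3.csv`, `signals.csv`, `soc_summary.csv`).
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Invisibly, the path of the written `report.md`.
#' @export
render_reports <- function(run_dir) {
  required <- c("table1.csv", "table2.csv", "table3.csv", "signals.csv",
                "soc_summary.csv", "manifest.json")
  missing <- required[!file.exists(file.path(run_dir, required))]
  if (length(missing)) {
    stop(sprintf("incomplete run directory, missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  signals <- utils::read.csv(file.path(run_dir, "signals.csv"))
  tab3 <- utils::read.csv(file.path(run_dir, "table3.csv"))
  lines <- c(
    "# Low-dose methotrexate renal-impairment risk: run report", "",
    sprintf("- report corpus signals flagged: %d of %d PTs",
            sum(signals$flag_signal), nrow(signals)),
    sprintf("- threshold table: table2.csv (%d rows)",
            nrow(utils::read.csv(file.path(run_dir, "table2.csv")))),
    sprintf("- optimized regimens: table3.csv (%d stage x dose rows)",
            nrow(tab3)),
    "", "Artifacts: table1.csv, table2.csv, table3.csv, signals.csv,",
    "soc_summary.csv, assessments.jsonl, manifest.json")
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
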