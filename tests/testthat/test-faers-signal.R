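test_that("drug-name normalization trims, ignores case, and passes unknowns through", {
  out <- normalize_drug_names(c("TREXALL", " mtx ", "unknownium", "Humira"))
  expect_equal(as.character(out),
               c("methotrexate", "methotrexate", "unknownium", "adalimumab"))
  expect_equal(attr(out, "n_unmatched"), 1L)
})

test_that("deduplication keeps the highest primary id per case and is idempotent", {
  cases <- make_cases(primary_id = c(10, 11, 20),
                      case_id = c(1, 1, 2),
                      drugs = list("methotrexate", "methotrexate", "ibuprofen"),
                      indication_pts = list("Renal failure", "Renal failure",
                                            "Psoriasis"),
                      reaction_pts = list("Nausea", c("Nausea", "Rash"),
                                          "Fatigue"))
  dd <- deduplicate_cases(cases)
  expect_equal(nrow(dd), 2L)
  expect_equal(dd$primary_id[dd$case_id == 1], 11)
  expect_equal(dd$reaction_pts[[which(dd$case_id == 1)]], c("Nausea", "Rash"))
  expect_identical(deduplicate_cases(dd)$primary_id, dd$primary_id)
})

test_that("non-ADR preferred terms are purged and empty cases dropped", {
  cases <- make_cases(primary_id = 1:3, case_id = 1:3,
                      drugs = list("methotrexate", "methotrexate", "ibuprofen"),
                      indication_pts = list("Renal failure", "Renal failure",
                                            "Renal failure"),
                      reaction_pts = list("Product quality issue",
                                          c("Thrombocytopenia", "Fall"),
                                          "Nausea"))
  out <- exclude_non_adr_pts(cases)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped_empty"), 1L)
  expect_equal(out$reaction_pts[[which(out$case_id == 2)]],
               "Thrombocytopenia")
  ident <- exclude_non_adr_pts(cases, excluded_pts = character(0))
  expect_equal(nrow(ident), 3L)
  expect_equal(ident$reaction_pts[[1]], "Product quality issue")
})

test_that("renal cohort filter keeps exactly the renal-indication cases", {
  cases <- make_cases(primary_id = 1:2, case_id = 1:2,
                      drugs = list("methotrexate", "methotrexate"),
                      indication_pts = list("Renal failure",
                                            "Rheumatoid arthritis"),
                      reaction_pts = list("Nausea", "Nausea"))
  out <- filter_renal_cohort(cases)
  expect_equal(out$case_id, 1)
  expect_error(filter_renal_cohort(cases, renal_pts = character(0)),
               "nonempty")
})

test_that("renal fraction of a generated corpus matches its plan", {
  plan <- signal_plan(n_cases = 10000, renal_fraction = 0.3, seed = 42)
  cases <- generate_faers_cases(plan)
  frac <- nrow(filter_renal_cohort(cases)) / nrow(cases)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("contingency cells match hand-counted values on a tiny corpus", {
  # 4 cases, pair counting: mtx cases carry {Nausea, Rash} and {Nausea};
  # non-mtx carry {Nausea} and {Rash, Fatigue}
  cases <- make_cases(primary_id = 1:4, case_id = 1:4,
                      drugs = list("methotrexate", "methotrexate",
                                   "ibuprofen", "ibuprofen"),
                      indication_pts = rep(list("Renal failure"), 4),
                      reaction_pts = list(c("Nausea", "Rash"), "Nausea",
                                          "Nausea", c("Rash", "Fatigue")))
  t_pair <- build_contingency(cases, "methotrexate", "Nausea")
  expect_equal(c(t_pair$a, t_pair$b, t_pair$c, t_pair$d), c(2, 1, 1, 2))
  expect_equal(t_pair$N, 6)
  t_case <- build_contingency(cases, "methotrexate", "Nausea", unit = "case")
  expect_equal(c(t_case$a, t_case$b, t_case$c, t_case$d), c(2, 0, 1, 1))
  absent <- build_contingency(cases, "warfarin", "Nausea")
  expect_true(absent$drug_absent)
  expect_equal(absent$a + absent$b, 0)
  nopt <- build_contingency(cases, "methotrexate", "Vomiting")
  expect_equal(nopt$a + nopt$c, 0)
})

test_that("PRR and chi-squared match hand arithmetic and the criterion rule", {
  t <- contingency_table(10, 90, 100, 9800)
  res <- compute_prr(t)
  expect_equal(res$prr, 9.9, tolerance = 1e-12)
  expect_equal(res$chi2, 73.5455, tolerance = 1e-4)
  expect_true(res$flag)
  # exact independence proportions
  ind <- compute_prr(contingency_table(5, 95, 50, 950))
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)
  expect_false(ind$flag)
  # frequency rule dominates even a huge PRR
  rare <- compute_prr(contingency_table(2, 1, 1, 10000))
  expect_gt(rare$prr, 100)
  expect_false(rare$flag)
  # zero margin is undefined, flagged invalid
  zm <- compute_prr(contingency_table(0, 0, 5, 5))
  expect_false(zm$valid)
  expect_false(zm$flag)
})

test_that("ROR and Wald interval match hand arithmetic; zero cells are corrected", {
  t <- contingency_table(10, 90, 100, 9800)
  res <- compute_ror(t)
  expect_equal(res$ror, 98000 / 9000, tolerance = 1e-12)
  expect_equal(res$ci_low, 5.503342, tolerance = 1e-6)
  expect_equal(res$ci_high, 21.544708, tolerance = 1e-6)
  expect_true(res$flag)
  expect_false(res$corrected)
  eq <- compute_ror(contingency_table(20, 50, 50, 20))
  expect_equal(eq$ror, (20 * 20) / (50 * 50))
  expect_false(eq$flag)
  z <- compute_ror(contingency_table(0, 10, 10, 100))
  expect_true(z$corrected)
  expect_equal(z$ror, (0.5 * 100.5) / (10.5 * 10.5))
})

test_that("information component and IC025 match hand arithmetic", {
  t <- contingency_table(10, 90, 100, 9800)
  res <- compute_ic(t)
  expect_equal(res$expected, 1.1)
  expect_equal(res$ic, log2(10.5 / 1.6), tolerance = 1e-12)
  expect_equal(res$ic025, 1.637061, tolerance = 1e-6)
  expect_true(res$flag)
  # near-exact independence at large N shrinks IC toward 0
  big <- compute_ic(contingency_table(100, 9900, 900, 89100))
  expect_lt(abs(big$ic), 0.02)
  expect_false(big$flag)
})

test_that("IC025 lies below IC for every table", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, lambda = c(5, 50, 50, 500)) + 1
    r <- compute_ic(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_lt(r$ic025, r$ic)
  }
})

test_that("Wald ROR interval has nominal coverage on simulated tables", {
  probs <- c(a = 0.03, b = 0.07, c = 0.15, d = 0.75)
  true_or <- (probs["a"] * probs["d"]) / (probs["b"] * probs["c"])
  set.seed(11)
  n_rep <- 2000
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cells <- as.vector(rmultinom(1, size = 500, prob = probs))
    r <- compute_ror(contingency_table(cells[1], cells[2], cells[3],
                                       cells[4]))
    covered[i] <- r$ci_low <= true_or && true_or <= r$ci_high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("closed-form IC025 tracks the gamma-posterior Monte-Carlo bound", {
  set.seed(5)
  for (a in c(5, 10, 20, 50)) {
    # tables with expectation near and below the observed count
    for (E in c(a / 2, a)) {
      ic <- log2((a + 0.5) / (E + 0.5))
      ic025_closed <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
      lam <- rgamma(2e5, shape = a + 0.5, rate = 1)
      ic025_mc <- unname(quantile(log2(lam / (E + 0.5)), 0.025))
      expect_lt(abs(ic025_closed - ic025_mc), 0.15)
    }
  }
})

test_that("signal listing is ordered by report count with SOC attached", {
  cases <- make_cases(
    primary_id = 1:6, case_id = 1:6,
    drugs = rep(list("methotrexate"), 6),
    indication_pts = rep(list("Renal failure"), 6),
    reaction_pts = list(c("Nausea", "Rash"), "Nausea", "Nausea",
                        c("Rash", "Alopecia"), "Rash", "Nausea"))
  sg <- detect_signals(cases, "methotrexate")
  expect_equal(sg$pt, c("Nausea", "Rash", "Alopecia"))
  expect_equal(sg$a, c(4, 3, 1))
  expect_equal(sg$soc[sg$pt == "Nausea"], "Gastrointestinal disorders")
  expect_true(all(sg$flag_signal == (sg$flag_prr & sg$flag_ror &
                                       sg$flag_bcpnn)))
})

test_that("SOC aggregation shares sum to one over flagged signals", {
  sg <- data.frame(pt = c("A", "B", "C"), soc = c("S1", "S1", "S2"),
                   flag_signal = TRUE)
  agg <- aggregate_by_soc(sg)
  expect_equal(agg$n_signals, c(2L, 1L))
  expect_equal(agg$share, c(2 / 3, 1 / 3))
  expect_equal(sum(agg$share), 1, tolerance = 1e-12)
  empty <- aggregate_by_soc(data.frame(pt = character(0),
                                       soc = character(0),
                                       flag_signal = logical(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("table loading round-trips, skips malformed lines, errors on empties", {
  plan <- signal_plan(n_cases = 200, dup_fraction = 0.1, seed = 3)
  td <- withr::local_tempdir()
  generate_faers_tables(plan, td)
  tabs <- load_faers_tables(td)
  # 200 cases + 20 duplicate versions in every file
  expect_equal(nrow(tabs$demo), 220L)
  expect_equal(length(unique(tabs$demo$caseid)), 200L)

  # corrupt one DRUG line -> one fewer row, with a warning
  lines <- readLines(file.path(td, "DRUG.txt"))
  lines[2] <- "only$two"
  writeLines(lines, file.path(td, "DRUG.txt"))
  expect_warning(tabs2 <- load_faers_tables(td), "malformed")
  expect_equal(nrow(tabs2$drug), length(lines) - 2L)

  writeLines("primaryid$caseid$drugname$dose_mg",
             file.path(td, "DRUG.txt"))
  expect_error(load_faers_tables(td), "DRUG")
})

test_that("cohort construction is deterministic for a fixed input directory", {
  plan <- signal_plan(n_cases = 300, seed = 9)
  td <- withr::local_tempdir()
  generate_faers_tables(plan, td)
  s1 <- detect_signals(build_cohort(td), "methotrexate")
  s2 <- detect_signals(build_cohort(td), "methotrexate")
  expect_identical(s1, s2)
})
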