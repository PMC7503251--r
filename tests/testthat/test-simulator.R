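small_scenario <- function(seed = 1L, n = 50L, ...) {
  er_scenario(n_patients = n, seed = seed, ...)
}

test_that("scenario validation names the offending field", {
  expect_error(er_scenario(ktas_mix = rep(0.2, 4)), "ktas_mix")
  expect_error(er_scenario(arrival_rates = rep(1, 10)), "arrival_rates")
  expect_error(er_scenario(n_patients = 0), "n_patients")
  bad_paths <- list(list(prob = 0.5, activities = c("Entry", "Discharge")))
  expect_error(er_scenario(pathways = bad_paths), "pathways")
})

test_that("the same seed reproduces a byte-identical log", {
  a <- simulate_erlog(small_scenario(7))
  b <- simulate_erlog(small_scenario(7))
  expect_identical(a$log, b$log)
  c <- simulate_erlog(small_scenario(8))
  expect_false(identical(a$log, c$log))
})

test_that("per-patient draws are stable when the cohort grows", {
  a <- simulate_erlog(small_scenario(3, n = 20))
  b <- simulate_erlog(small_scenario(3, n = 40))
  a_p1 <- as.data.frame(a$log[a$log$patient_id == "P000001", ])
  b_p1 <- as.data.frame(b$log[b$log$patient_id == "P000001", ])
  expect_equal(a_p1, b_p1)
})

test_that("degenerate deterministic services give exact stay lengths", {
  paths <- list(list(prob = 1, activities = c("Entry", "Treatment", "Discharge")))
  st <- c("Entry" = 600, "Treatment" = 600, "Discharge" = 600)
  cfg <- er_scenario(n_patients = 30, seed = 5, pathways = paths,
                     service_times = st, service_family = "deterministic",
                     ktas_multipliers = rep(1, 5), revisit_prob = 0,
                     cost_rates = NULL)
  sim <- simulate_erlog(cfg)
  expect_true(all(los(sim$log)$seconds == 1200))  # two 10-min services
  expect_equal(sim$truth$expected_los, 1200)
})

test_that("simulated logs are clean, complete-typed and well-formed", {
  sim <- simulate_erlog(small_scenario(11, n = 80))
  log <- sim$log
  expect_true(all(log$event_type == "complete"))
  expect_true(all(!is.na(log$resource)))
  expect_true(all(log$emergency %in% 1:5))
  expect_true(all(table(log$case_id) >= 2))
  # preprocessing finds nothing to remove
  expect_equal(nrow(remove_imperfect_cases(log, "entry")$report), 0L)
  expect_equal(deduplicate_collateral(log)$removed, 0L)
  # every variant is a configured pathway
  expect_true(all(unique(case_variants(log)) %in%
                    names(sim$truth$variant_probs)))
})

test_that("mean LOS converges to the analytic scenario expectation", {
  sim <- simulate_erlog(small_scenario(42, n = 2000))
  s <- los(sim$log)$seconds
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - sim$truth$expected_los), 3 * se)
})

test_that("variant frequencies converge to pathway probabilities", {
  sim <- simulate_erlog(small_scenario(13, n = 2000))
  lang <- log_language(sim$log)
  v <- vapply(lang$variants, paste, character(1), collapse = " > ")
  truth <- sim$truth$variant_probs
  tv <- sum(abs(lang$p - truth[v])) / 2
  expect_lt(tv, 0.05)
})

test_that("rule-consistent vitals give perfect accuracy at zero noise", {
  sim <- simulate_erlog(small_scenario(19, n = 150))
  log <- simulate_vitals(sim$log, noise = 0, seed = 2)
  expect_equal(as.numeric(triage_accuracy(log)), 1)
  expect_equal(attr(log, "truth")$expected_accuracy, 1)
})

test_that("forced disagreement drives accuracy to zero", {
  sim <- simulate_erlog(small_scenario(19, n = 100))
  log <- simulate_vitals(sim$log, noise = 1, seed = 2)
  expect_equal(as.numeric(triage_accuracy(log)), 0)
})

test_that("vitals are reproducible and rule-consistent per level", {
  sim <- simulate_erlog(small_scenario(23, n = 100))
  a <- simulate_vitals(sim$log, noise = 0.2, seed = 9)
  b <- simulate_vitals(sim$log, noise = 0.2, seed = 9)
  expect_identical(attr(a, "vitals"), attr(b, "vitals"))
  expect_identical(a$emergency, b$emergency)
})

test_that("imperfection injection round trips through preprocessing", {
  sim <- simulate_erlog(small_scenario(29, n = 120))
  cfg <- er_imperfections(collateral_dup_rate = 0.01,
                          time_travel_case_count = 5L,
                          form_based_case_count = 4L,
                          multi_visit_same_day_count = 2L)
  inj <- inject_imperfections(sim$log, cfg, seed = 3)
  man <- inj$manifest
  expect_equal(sum(man$pattern == "time_travel"), 5L)
  expect_equal(sum(man$pattern == "form_based"), 4L)
  expect_equal(sum(man$pattern == "exclusive_case"), 2L)
  n_dups <- sum(man$pattern == "collateral")
  expect_equal(n_dups, round(0.01 * nrow(sim$log)))

  dd <- deduplicate_collateral(inj$log)
  expect_equal(dd$removed, n_dups)
  rm <- remove_imperfect_cases(dd$log, "entry")
  expect_setequal(rm$report$case_id,
                  man$case_id[man$pattern %in% c("time_travel", "form_based")])
  expect_equal(sort(paste(rm$report$case_id, rm$report$pattern)),
               sort(paste(man$case_id[man$pattern %in% c("time_travel", "form_based")],
                          man$pattern[man$pattern %in% c("time_travel", "form_based")])))
  # the surviving cases are exactly the clean log minus the deleted ones
  expect_setequal(unique(rm$log$case_id),
                  unique(sim$log$case_id)[!unique(sim$log$case_id) %in% rm$report$case_id])
})

test_that("zero-config injection leaves the log unchanged", {
  sim <- simulate_erlog(small_scenario(31, n = 30))
  inj <- inject_imperfections(sim$log, er_imperfections(), seed = 1)
  expect_identical(as.data.frame(inj$log), as.data.frame(sim$log))
  expect_equal(nrow(inj$manifest), 0L)
})

test_that("infeasible injection counts are rejected", {
  sim <- simulate_erlog(small_scenario(37, n = 10))
  expect_error(
    inject_imperfections(sim$log,
                         er_imperfections(time_travel_case_count = 1000L)),
    "infeasible")
})
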