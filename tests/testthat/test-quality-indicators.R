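test_that("LOS standard deviation is the population form", {
  same <- as_erlog(data.frame(
    case_id = rep(1:3, each = 2), activity = "A",
    timestamp = rep(c(0, 3600), 3) + rep(c(0, 10000, 20000), each = 2)))
  expect_equal(los_std(same), 0)
  two <- as_erlog(data.frame(
    case_id = rep(1:2, each = 2), activity = "A",
    timestamp = c(0, 3600, 10000, 10000 + 3 * 3600)))
  expect_equal(los_std(two), 3600)  # population sd of {1h, 3h}
  one <- as_erlog(data.frame(case_id = 1, activity = "A", timestamp = 0))
  expect_error(los_std(one), "at least 2")
})

test_that("workload follows the started-minus-completed recursion", {
  # one event starting in bin 1 and completing in bin 2
  log <- as_erlog(data.frame(
    case_id = 1, activity = c("A", "B"),
    timestamp = c(1800, 4000), resource = c("r", "r")))
  g <- time_grid(0, 3600, 3)
  wl <- workload(log, "r", g)
  # A: zero-duration first event in bin 1; B: starts 1800 (bin 1),
  # completes 4000 (bin 2)
  expect_equal(wl$started, c(2L, 0L, 0L))
  expect_equal(wl$completed, c(1L, 1L, 0L))
  expect_equal(wl$workload, c(1L, 0L, 0L))
  # event starting and completing in bin 1 contributes nothing on net
  log2 <- as_erlog(data.frame(case_id = 1, activity = c("A", "B"),
                              timestamp = c(100, 200), resource = "r"))
  expect_equal(workload(log2, "r", g)$workload, c(0L, 0L, 0L))
  expect_error(workload(log, "nurse", g), "unknown resource")
})

test_that("workload telescopes: final bin equals started minus completed", {
  for (seed in 1:5) {
    log <- random_erlog(seed, n_cases = 15)
    g <- time_grid_for(log, 6 * 3600)
    for (r in unique(log$resource)) {
      wl <- workload(log, r, g)
      expect_equal(wl$workload, cumsum(wl$started - wl$completed))
      expect_equal(wl$workload[g$n], sum(wl$started) - sum(wl$completed))
    }
  }
})

test_that("patient-census workload mode mirrors resources_per_period", {
  log <- random_erlog(9, n_cases = 10)
  g <- time_grid_for(log, 6 * 3600)
  wl <- workload(log, "patient_census", g)
  expect_equal(wl$workload, resources_per_period(log, g)$patient_count)
})

test_that("the log language is the variant frequency distribution", {
  lang <- log_language(snippet_log())
  v <- vapply(lang$variants, paste, character(1), collapse = " > ")
  expect_setequal(v, c("Entry > Treatment > Consultation", "Entry > Treatment"))
  expect_equal(lang$p, c(0.5, 0.5))
  single <- log_language(as_erlog(data.frame(case_id = 1, activity = "A",
                                             timestamp = 0)))
  expect_equal(single$p, 1)
  for (seed in 1:3) {
    lang <- log_language(random_erlog(seed))
    expect_equal(sum(lang$p), 1)
  }
  expect_error(stoch_lang(list(c("a")), 0.9), "sum to 1")
})

test_that("stochastic language CSV round trips", {
  lang <- random_language(3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_stoch_lang(lang, tmp)
  back <- read_stoch_lang(tmp)
  expect_equal(back$variants, lang$variants)
  expect_equal(back$p, lang$p)
})

test_that("matching rate reproduces hand-computed cases", {
  a <- stoch_lang(list(c("a", "b")), 1)
  b <- stoch_lang(list(c("a", "c")), 1)
  expect_equal(matching_rate(a, b), 0.5)  # one substitution over length 2
  expect_equal(matching_rate(a, a), 1)
  lang <- log_language(snippet_log())
  expect_equal(matching_rate(lang, lang), 1)
})

test_that("matching rate is symmetric and bounded", {
  for (seed in 1:20) {
    x <- random_language(seed)
    y <- random_language(seed + 1000)
    mr_xy <- matching_rate(x, y)
    mr_yx <- matching_rate(y, x)
    expect_equal(mr_xy, mr_yx, tolerance = 1e-12)
    expect_gte(mr_xy, 0)
    expect_lte(mr_xy, 1)
    expect_equal(matching_rate(x, x), 1)
  }
})

test_that("normalized Levenshtein matches an independent DP oracle", {
  set.seed(99)
  for (i in 1:30) {
    a <- sample(letters[1:5], sample.int(6, 1), replace = TRUE)
    b <- sample(letters[1:5], sample.int(6, 1), replace = TRUE)
    d <- erppi:::normalized_levenshtein(list(a), list(b))[1, 1]
    expect_equal(d, bf_levenshtein(a, b) / max(length(a), length(b)))
  }
})

test_that("triage classification is deterministic and reaches all levels", {
  rules <- triage_rules_synthetic()
  vit <- data.frame(gcs = c(5, 15, 15, 15, 15),
                    spo2 = c(98, 88, 98, 98, 98),
                    sbp = c(120, 120, 120, 120, 120),
                    pulse = c(80, 80, 80, 80, 80),
                    resp = c(14, 14, 14, 14, 14),
                    temp = c(36.8, 36.8, 36.8, 36.8, 36.8),
                    pain = c(0, 0, 8, 5, 1))
  expect_equal(triage_classify(vit, rules), c(1L, 2L, 3L, 4L, 5L))
  expect_equal(triage_classify(vit, rules), triage_classify(vit, rules))
})

test_that("triage rule JSON round trips", {
  rules <- triage_rules_synthetic()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_triage_rules(rules, tmp)
  back <- read_triage_rules(tmp)
  vit <- data.frame(gcs = 15, spo2 = 91, sbp = 120, pulse = 80, resp = 14,
                    temp = 36.8, pain = 2)
  expect_equal(triage_classify(vit, back), triage_classify(vit, rules))
})

test_that("triage accuracy compares classifier output to recorded levels", {
  log <- random_erlog(21, n_cases = 40)
  ct <- erppi:::case_table(log)
  vitals <- data.frame(case_id = ct$case_id, level = ct$emergency)
  # identity classifier
  acc <- triage_accuracy(log, classifier = function(v) v$level,
                         vitals = vitals)
  expect_equal(as.numeric(acc), 1)
  conf <- attr(acc, "confusion")
  expect_equal(sum(diag(conf)), sum(conf))
  # constant classifier scores the label frequency
  acc3 <- triage_accuracy(log, classifier = function(v) rep(3L, nrow(v)),
                          vitals = vitals)
  expect_equal(as.numeric(acc3), mean(ct$emergency == 3L))
  expect_error(triage_accuracy(log), "no vital features")
})

test_that("response rate flags overtaken less-urgent arrivals (printed form)", {
  # snippet: t1,2 = 19:17 < t2,2 = 19:36, no violation
  tpr <- triage_response_rate(snippet_log())
  expect_equal(tpr$rate, 1)
  # all equal urgency: strict inequality never holds
  eq <- as_erlog(data.frame(
    case_id = rep(1:3, each = 2), activity = rep(c("Entry", "Care"), 3),
    timestamp = c(0, 100, 200, 300, 400, 500), emergency = 2))
  expect_equal(triage_response_rate(eq)$rate, 1)
  # an overtaking pair with the printed urgency relation
  viol <- as_erlog(data.frame(
    case_id = rep(1:2, each = 2), activity = rep(c("Entry", "Care"), 2),
    timestamp = c(0, 500, 100, 300),       # case 1 arrives first, served later
    emergency = rep(c(4, 2), each = 2)))   # case 1 less urgent (higher KTAS)
  expect_equal(triage_response_rate(viol)$rate, 0)   # 1 - 1/(2-1)
  # flipped direction: same log is compliant
  expect_equal(triage_response_rate(viol, direction = "urgency")$rate, 1)
})

test_that("response and revisit rates are translation invariant", {
  log <- random_erlog(31, n_cases = 30)
  shift <- as.data.frame(log)
  shift$timestamp <- shift$timestamp + 86400 * 30
  shifted <- as_erlog(shift)
  expect_equal(triage_response_rate(log)$rate,
               triage_response_rate(shifted)$rate)
  expect_equal(as.numeric(revisit_rate(log, 7200)),
               as.numeric(revisit_rate(shifted, 7200)))
})

test_that("revisit rate counts same-patient pairs within the window", {
  expect_equal(as.numeric(revisit_rate(snippet_log())), 0)
  # one patient, two cases 2 h apart (end to start)
  two <- as_erlog(data.frame(
    case_id = rep(c("a", "b"), each = 2), activity = "A",
    timestamp = c(0, 3600, 3600 + 7200, 3600 + 7200 + 1800),
    patient_id = "P1"))
  expect_equal(as.numeric(revisit_rate(two, 86400)), 1)
  expect_equal(attr(revisit_rate(two, 86400), "pairs"), 1L)
  # boundary: a gap of exactly the window is counted
  expect_equal(as.numeric(revisit_rate(two, 7200)), 1)
  expect_equal(as.numeric(revisit_rate(two, 7199)), 0)
  # start-to-start mode measures from the earlier case's start
  expect_equal(as.numeric(revisit_rate(two, 7200, mode = "start_to_start")), 0)
  expect_equal(as.numeric(revisit_rate(two, 3600 + 7200,
                                       mode = "start_to_start")), 1)
})
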