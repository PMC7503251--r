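test_that("CSV reader parses the ER snippet into the expected log", {
  path <- system.file("extdata", "er_snippet.csv", package = "erppi")
  log <- read_erlog_csv(path)
  expect_s3_class(log, "erlog")
  expect_equal(nrow(log), 5L)
  expect_equal(n_cases(log), 2L)
  expect_setequal(activities(log), c("Entry", "Treatment", "Consultation"))
  expect_equal(log$timestamp[1], epoch("2018-02-01 19:05:00"))
  expect_equal(log$event_type, c("complete", "complete", "start",
                                 "complete", "complete"))
  expect_equal(log$emergency[log$case_id == "2"], c(1L, 1L))
})

test_that("CSV reader handles empty logs, bad timestamps and bad columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("CaseID,Activity,Timestamp", tmp)
  log <- read_erlog_csv(tmp)
  expect_equal(nrow(log), 0L)
  expect_equal(n_cases(log), 0L)

  writeLines(c("CaseID,Activity,Timestamp", "1,Entry,not-a-date"), tmp)
  expect_error(read_erlog_csv(tmp), "line")

  writeLines(c("CaseID,Activity", "1,Entry"), tmp)
  expect_error(read_erlog_csv(tmp), "mandatory")
})

test_that("emergency values outside 1-5 are rejected or coerced on request", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CaseID,Activity,Timestamp,Emergency",
               "1,Entry,2018-02-01 10:00:00,7"), tmp)
  expect_error(read_erlog_csv(tmp), "emergency")
  log <- read_erlog_csv(tmp, on_invalid_emergency = "na")
  expect_true(is.na(log$emergency[1]))
})

test_that("events with identical timestamps keep stable input order", {
  log <- as_erlog(data.frame(
    case_id = c("a", "a"), activity = c("X", "Y"),
    timestamp = c(100, 100)))
  expect_equal(n_cases(log), 1L)
  expect_equal(log$activity, c("X", "Y"))
})

test_that("ISO 8601 timestamps are auto-detected alongside dd/mm dialect", {
  log <- as_erlog(data.frame(
    case_id = 1:2, activity = "A",
    timestamp = c("2018-02-01T19:05:00", "2018-02-01 19:05")))
  expect_equal(log$timestamp, rep(epoch("2018-02-01 19:05:00"), 2))
})

test_that("CSV round trip reproduces the log field-for-field", {
  log <- snippet_log()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_erlog_csv(log, tmp)
  back <- read_erlog_csv(tmp)
  for (col in c("case_id", "activity", "timestamp", "event_type",
                "resource", "emergency", "patient_id")) {
    expect_equal(back[[col]], log[[col]], info = col)
  }
})

test_that("XES round trip preserves all mapped fields", {
  log <- random_erlog(11, n_cases = 6)
  tmp <- withr::local_tempfile(fileext = ".xes")
  write_erlog_xes(log, tmp)
  back <- read_erlog_xes(tmp)
  for (col in c("case_id", "activity", "timestamp", "event_type",
                "resource", "emergency", "patient_id")) {
    expect_equal(back[[col]], log[[col]], info = col)
  }
})

test_that("malformed XES is rejected with the offending trace named", {
  tmp <- withr::local_tempfile(fileext = ".xes")
  writeLines(c('<?xml version="1.0"?>', "<log>",
               '<trace><string key="concept:name" value="t1"/></trace>',
               "</log>"), tmp)
  expect_error(read_erlog_xes(tmp), "trace 1")
})

test_that("patient_visit case building splits on the gap threshold", {
  ev <- data.frame(
    case_id = "raw", activity = c("Entry", "Treatment", "Entry"),
    timestamp = epoch("2018-02-01 09:00:00") + c(0, 1800, 25 * 3600),
    patient_id = "P1", stringsAsFactors = FALSE)
  out <- build_cases(ev, "patient_visit", visit_gap = 6 * 3600)
  expect_equal(n_cases(out), 2L)
  # same events, given ids: one case
  expect_equal(n_cases(build_cases(ev, "given_case_id")), 1L)
  # single event
  one <- build_cases(ev[1, ], "patient_visit")
  expect_equal(n_cases(one), 1L)
})

test_that("patient_visit cases never mix patients", {
  set.seed(42)
  ev <- data.frame(
    case_id = "raw",
    activity = "A",
    timestamp = epoch("2018-02-01") + sort(sample.int(86400 * 5, 60)),
    patient_id = sample(c("P1", "P2", "P3"), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  out <- build_cases(ev, "patient_visit", visit_gap = 3600)
  per_case <- tapply(out$patient_id, out$case_id,
                     function(p) length(unique(p)))
  expect_true(all(per_case == 1L))
  expect_error(build_cases(ev[, setdiff(names(ev), "patient_id")],
                           "patient_visit"),
               "patient_id")
})

test_that("start-time inference follows the preceding-complete rule", {
  log <- snippet_log()
  iv <- infer_start_times(log)
  treat <- iv[iv$case_id == "1" & iv$activity == "Treatment", ]
  expect_equal(treat$start_time, epoch("2018-02-01 19:05:00"))
  expect_equal(treat$complete_time, epoch("2018-02-01 19:17:00"))
  firsts <- iv[!duplicated(iv$case_id), ]
  expect_true(all(firsts$duration == 0))
  expect_true(all(iv$duration >= 0))
})

test_that("explicit start/complete pairs keep their recorded interval", {
  log <- as_erlog(data.frame(
    case_id = 1, activity = c("A", "B", "B"),
    timestamp = epoch("2018-02-01 19:00:00") + c(0, 1200, 2100),
    event_type = c("complete", "start", "complete")))
  iv <- infer_start_times(log)
  expect_equal(nrow(iv), 2L)  # paired start is lifecycle metadata
  b <- iv[iv$activity == "B", ]
  expect_equal(b$duration, 900)
})

test_that("variants and aggregation functions follow their definitions", {
  log <- snippet_log()
  expect_equal(variant_of(log[log$case_id == "1", ]),
               c("Entry", "Treatment", "Consultation"))
  expect_equal(unname(case_variants(log)),
               c("Entry > Treatment > Consultation", "Entry > Treatment"))
  expect_equal(aggregate_samples(5, "med"), 5)
  expect_equal(aggregate_samples(c(1, 2, 3, 4), "avg"), 2.5)
  expect_equal(aggregate_samples(c(1, 2, 3, 4), "std"), sqrt(1.25))
  expect_equal(aggregate_samples(c(1, 2, 3, 4), "std", sd_type = "sample"),
               sd(c(1, 2, 3, 4)))
  expect_equal(aggregate_samples(c(3, 9), "min"), 3)
  expect_equal(aggregate_samples(c(3, 9), "max"), 9)
  expect_error(aggregate_samples(numeric(0), "avg"), "no measurements")
})
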