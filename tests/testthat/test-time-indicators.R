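test_that("length of stay matches the snippet timestamps", {
  log <- snippet_log()
  s <- los(log)
  expect_equal(s$seconds, c(900, 900))  # 15 min each
  single <- as_erlog(data.frame(case_id = 1, activity = "Entry",
                                timestamp = 100))
  expect_equal(los(single)$seconds, 0)
})

test_that("variant-restricted LOS selects exactly the matching cases", {
  log <- snippet_log()
  s <- los_by_variant(log, c("Entry", "Treatment"))
  expect_equal(s$case_id, "2")
  expect_equal(s$seconds, 900)
  # selector matching all cases reproduces los()
  all_s <- los_by_variant(log, function(a) TRUE)
  expect_equal(all_s, los(log))
  # no match is an empty sample, not an error
  none <- los_by_variant(log, c("Entry"))
  expect_equal(nrow(none), 0L)
})

test_that("terminal-activity split partitions the log's LOS mean", {
  log <- random_erlog(5, n_cases = 40)
  all_s <- los(log)
  last_act <- vapply(strsplit(all_s$variant, " > ", fixed = TRUE),
                     function(a) a[length(a)], character(1))
  groups <- split(all_s$seconds, last_act)
  weighted <- sum(vapply(groups, sum, numeric(1))) / nrow(all_s)
  expect_equal(weighted, mean(all_s$seconds))
  for (lab in names(groups)) {
    grp <- los_by_variant(log, ends_with_activity(lab))
    expect_equal(sort(grp$seconds), sort(groups[[lab]]))
  }
})

test_that("emergency-restricted LOS honours levels and presets", {
  log <- snippet_log()
  s1 <- los_by_emergency(log, 1L)
  expect_equal(s1$case_id, "2")
  expect_equal(los_by_emergency(log, 1:5)$seconds, los(log)$seconds)
  expect_equal(los_by_emergency(log, "severe")$case_id, "2")
  expect_equal(los_by_emergency(log, "moderate")$case_id, "1")
  expect_equal(nrow(los_by_emergency(log, "mild")), 0L)
  expect_error(los_by_emergency(log, integer(0)), "non-empty")
  expect_error(los_by_emergency(log, 6L), "non-empty|subset")
})

test_that("emergency presets partition a fully-labelled log", {
  log <- random_erlog(7, n_cases = 50)
  parts <- lapply(c("severe", "moderate", "mild"),
                  function(g) los_by_emergency(log, g)$case_id)
  expect_setequal(unlist(parts), los(log)$case_id)
  expect_equal(sum(lengths(parts)), n_cases(log))
})

test_that("cycle time enumerates occurrences with successors", {
  log <- snippet_log()
  expect_equal(cycle_time(log, "Entry")$seconds, c(720, 900))
  # case-final activity yields no sample
  expect_equal(nrow(cycle_time(log, "Consultation")), 0L)
  expect_error(cycle_time(log, "Surgery"), "unknown activity")
  # two occurrences in one case give two samples
  rep2 <- as_erlog(data.frame(
    case_id = 1, activity = c("A", "B", "A", "B"),
    timestamp = c(0, 10, 30, 70)))
  expect_equal(cycle_time(rep2, "A")$seconds, c(10, 40))
})

test_that("cycle times telescope to the length of stay", {
  for (seed in 1:5) {
    log <- random_erlog(seed, n_cases = 25)
    per_case_gap <- rep(0, n_cases(log))
    names(per_case_gap) <- los(log)$case_id
    for (a in activities(log)) {
      s <- cycle_time(log, a)
      if (nrow(s)) {
        add <- tapply(s$seconds, s$case_id, sum)
        per_case_gap[names(add)] <- per_case_gap[names(add)] + add
      }
    }
    expect_equal(per_case_gap, setNames(los(log)$seconds, los(log)$case_id))
  }
})

test_that("initial response time measures entry to its successor", {
  log <- snippet_log()
  s <- initial_response_time(log)
  expect_equal(s$seconds, c(720, 900))  # 12 and 15 min
  expect_equal(sum(attr(s, "skipped")), 0L)
  only_entry <- as_erlog(data.frame(case_id = 1, activity = "Entry",
                                    timestamp = 0))
  s2 <- initial_response_time(only_entry)
  expect_equal(nrow(s2), 0L)
  expect_equal(unname(attr(s2, "skipped")["no_successor"]), 1L)
})

test_that("door-to-doctor uses first entry and first consultation", {
  log <- snippet_log()
  s <- door_to_doctor_time(log)
  expect_equal(s$case_id, "1")
  expect_equal(s$seconds, 900)
  expect_equal(attr(s, "skipped"), 1L)  # case 2 has no consultation
  # repeated consultations: first occurrence by default, last on request
  twice <- as_erlog(data.frame(
    case_id = 1, activity = c("Entry", "Consultation", "Consultation"),
    timestamp = c(0, 300, 900)))
  expect_equal(door_to_doctor_time(twice)$seconds, 300)
  expect_equal(door_to_doctor_time(twice, use = "last")$seconds, 900)
})

test_that("per-case indicators account for every case (samples + skipped)", {
  for (seed in 6:8) {
    log <- random_erlog(seed, n_cases = 30,
                        activities = c("Consultation", "Treatment"))
    s <- door_to_doctor_time(log)
    expect_equal(nrow(s) + attr(s, "skipped"), n_cases(log))
    irt <- initial_response_time(log)
    expect_equal(nrow(irt) + sum(attr(irt, "skipped")), n_cases(log))
    expect_true(all(s$seconds >= 0))
    expect_true(all(irt$seconds >= 0))
  }
})
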