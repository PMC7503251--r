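# Fixtures built in code.

# The canonical 5-row / 2-case ER snippet (dd/mm/yyyy timestamps; the
# third event is a lifecycle "start" with no complete partner).
snippet_events <- function() {
  data.frame(
    CaseID = c(1, 1, 1, 2, 2),
    Activity = c("Entry", "Treatment", "Consultation", "Entry", "Treatment"),
    Timestamp = c("01/02/2018 19:05", "01/02/2018 19:17", "01/02/2018 19:20",
                  "01/02/2018 19:21", "01/02/2018 19:36"),
    Type = c("Complete", "Complete", "Start", "Complete", "Complete"),
    Resource = c("John", "Jane", "Tom", "John", "Jane"),
    Emergency = c(3, 3, 3, 1, 1),
    PatientID = c("P1", "P1", "P1", "P2", "P2"),
    stringsAsFactors = FALSE)
}

snippet_log <- function() {
  ev <- snippet_events()
  as_erlog(data.frame(case_id = ev$CaseID, activity = ev$Activity,
                      timestamp = as_epoch(ev$Timestamp),
                      event_type = ev$Type, resource = ev$Resource,
                      emergency = ev$Emergency, patient_id = ev$PatientID,
                      stringsAsFactors = FALSE))
}

as_epoch <- function(x) {
  as.numeric(as.POSIXct(strptime(x, "%d/%m/%Y %H:%M", tz = "UTC")))
}

epoch <- function(iso) as.numeric(as.POSIXct(iso, tz = "UTC"))

# Small random complete-only log with integer-second timestamps; used for
# property tests. Activities drawn from a small pool; every case starts
# with Entry.
random_erlog <- function(seed, n_cases = 20, max_events = 8,
                         activities = c("Triage", "Treatment", "Test",
                                        "Consultation", "Discharge"),
                         resources = c("r1", "r2", "r3"),
                         n_patients = max(2, n_cases %/% 2)) {
  set.seed(seed)
  rows <- lapply(seq_len(n_cases), function(k) {
    m <- sample.int(max_events, 1)
    t0 <- epoch("2018-03-01") + sample.int(14 * 86400, 1)
    times <- t0 + cumsum(c(0, sample.int(3600, m - 1, replace = TRUE)))
    data.frame(case_id = sprintf("c%03d", k),
               activity = c("Entry", sample(activities, m - 1, replace = TRUE)),
               timestamp = times,
               event_type = "complete",
               resource = sample(resources, m, replace = TRUE),
               emergency = sample.int(5, 1),
               patient_id = sprintf("p%03d", sample.int(n_patients, 1)),
               stringsAsFactors = FALSE)
  })
  as_erlog(do.call(rbind, rows))
}
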