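#' Group flat events into cases
#'
#' With `strategy = "given_case_id"` the recorded case ids are trusted.
#' With `strategy = "patient_visit"` cases are rebuilt as patient visits
#' (the remedy for the "exclusive case" imperfection pattern, where the raw
#' case identifier is the patient id and same-day revisits collapse into
#' one case): consecutive events of one patient separated by more than
#' `visit_gap` start a new case, and the new case id is the patient id
#' joined with the first event's timestamp.
#'
#' @param events an `erlog` or event data frame.
#' @param strategy `"given_case_id"` or `"patient_visit"`.
#' @param visit_gap gap threshold in seconds between consecutive events of
#'   one patient that starts a new visit (default 24 h).
#' @return an `erlog` with rebuilt `case_id`s.
#' @export
build_cases <- function(events, strategy = c("given_case_id", "patient_visit"),
                        visit_gap = 24 * 3600) {
  strategy <- match.arg(strategy)
  log <- if (inherits(events, "erlog")) events else as_erlog(events)
  if (strategy == "given_case_id") return(log)
  if (anyNA(log$patient_id)) {
    stop("patient_visit case building requires patient_id on every event",
         call. = FALSE)
  }
  ord <- order(match(log$patient_id, unique(log$patient_id)), log$timestamp,
               seq_len(nrow(log)), method = "radix")
  log <- log[ord, , drop = FALSE]
  new_patient <- !duplicated(log$patient_id)
  gap <- c(0, diff(log$timestamp))
  new_visit <- new_patient | gap > visit_gap
  visit_id <- cumsum(new_visit)
  first_ts <- log$timestamp[new_visit][visit_id]
  log$case_id <- paste(log$patient_id, format_epoch(first_ts, "%Y%m%dT%H%M%S"),
                       sep = "_")
  as_erlog(as.data.frame(log))
}

#' Remove cases matching deletion-remedy imperfection patterns
#'
#' Deletes every case containing (a) an event timestamped strictly before
#' the case's ER-entry event ("inadvertent time travel" -- e.g. a
#' diagnostic test recorded before arrival), or (b) at least
#' `form_threshold` events with distinct activities sharing one identical
#' timestamp ("form-based event capture"). Deletion mirrors the remedy
#' applied in practice: the patterns affect few cases and cannot be
#' repaired reliably.
#'
#' @param log an `erlog`.
#' @param entry_activity label of the ER-entry activity (matched
#'   case-insensitively after trimming). Cases with no entry event are left
#'   untouched by the time-travel check.
#' @param form_threshold minimum number of distinct activities at one
#'   instant that flags form-based capture (default 3).
#' @return a list with `log` (the cleaned `erlog`) and `report` (data frame
#'   of `case_id`, `pattern` for every removed case).
#' @export
remove_imperfect_cases <- function(log, entry_activity = "entry",
                                   form_threshold = 3L) {
  entry <- norm_label(entry_activity)
  act <- norm_label(log$activity)
  if (nrow(log) && !entry %in% act) {
    stop(sprintf("entry activity '%s' not in the activity alphabet (%s)",
                 entry_activity, paste(activities(log), collapse = ", ")),
         call. = FALSE)
  }
  cid <- factor(log$case_id, levels = unique(log$case_id))

  # time travel: any event strictly before the case's first entry event
  is_entry <- act == entry
  entry_time <- rep(NA_real_, nlevels(cid))
  if (any(is_entry)) {
    et <- tapply(log$timestamp[is_entry], cid[is_entry], min)
    entry_time[match(names(et), levels(cid))] <- as.numeric(et)
  }
  before_entry <- !is.na(entry_time[as.integer(cid)]) &
    log$timestamp < entry_time[as.integer(cid)]
  tt_cases <- levels(cid)[unique(as.integer(cid)[before_entry])]

  # form-based capture: >= form_threshold distinct activities at one instant
  key <- paste(as.integer(cid), log$timestamp, sep = "\r")
  dk <- !duplicated(paste(key, act, sep = "\r"))   # distinct activity per (case, instant)
  cnt <- table(key[dk])
  fb_keys <- names(cnt)[cnt >= form_threshold]
  fb_cases <- setdiff(
    levels(cid)[unique(as.integer(cid)[key %in% fb_keys])], tt_cases)

  report <- rbind(
    data.frame(case_id = tt_cases,
               pattern = rep("time_travel", length(tt_cases)),
               stringsAsFactors = FALSE),
    data.frame(case_id = fb_cases,
               pattern = rep("form_based", length(fb_cases)),
               stringsAsFactors = FALSE))
  keep <- !(log$case_id %in% report$case_id)
  out <- log[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(log = out, report = report)
}

#' Collapse collateral duplicate events
#'
#' Events within a case that are identical on activity, timestamp, event
#' type and originator are duplicates ("collateral events"); only the first
#' is retained.
#'
#' @param log an `erlog`.
#' @return list with `log` (deduplicated `erlog`) and `removed` (number of
#'   events deleted).
#' @export
deduplicate_collateral <- function(log) {
  key <- paste(log$case_id, norm_label(log$activity), log$timestamp,
               log$event_type, log$resource, sep = "\r")
  dup <- duplicated(key)
  out <- log[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(log = out, removed = sum(dup))
}
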