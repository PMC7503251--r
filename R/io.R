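#' Column mapping for CSV event logs
#'
#' Maps the canonical event-log fields to source column names. The defaults
#' match the usual ER log headers (`CaseID`, `Activity`, `Timestamp`,
#' `Type`, `Resource`, `Emergency`, `PatientID`, `Cost`). `case_id`,
#' `activity` and `timestamp` are mandatory; the rest may be `NA` (absent
#' in the file).
#'
#' @param case_id,activity,timestamp,event_type,resource,emergency,patient_id,cost
#'   source column names (or `NA` for optional ones).
#' @param timestamp_format strptime format for non-ISO timestamps. The
#'   default is day-first `"%d/%m/%Y %H:%M"`; ISO 8601 timestamps are
#'   auto-detected regardless of this setting.
#' @return a list of class `er_colmap`.
#' @export
er_colmap <- function(case_id = "CaseID", activity = "Activity",
                      timestamp = "Timestamp", event_type = "Type",
                      resource = "Resource", emergency = "Emergency",
                      patient_id = "PatientID", cost = "Cost",
                      timestamp_format = "%d/%m/%Y %H:%M") {
  structure(list(case_id = case_id, activity = activity,
                 timestamp = timestamp, event_type = event_type,
                 resource = resource, emergency = emergency,
                 patient_id = patient_id, cost = cost,
                 timestamp_format = timestamp_format),
            class = "er_colmap")
}

#' Read an ER event log from CSV
#'
#' @param path path to a CSV file with a header row (UTF-8; quoted fields
#'   allowed).
#' @param colmap an [er_colmap()] describing the source columns.
#' @param on_invalid_emergency passed to [as_erlog()].
#' @return an `erlog`.
#' @examples
#' p <- system.file("extdata", "er_snippet.csv", package = "erppi")
#' log <- read_erlog_csv(p)
#' @export
read_erlog_csv <- function(path, colmap = er_colmap(),
                           on_invalid_emergency = c("error", "na")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         encoding = "UTF-8")
  mandatory <- c("case_id", "activity", "timestamp")
  for (f in mandatory) {
    src <- colmap[[f]]
    if (is.na(src) || !src %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (mapped to field '%s') missing from %s",
                   src, f, path), call. = FALSE)
    }
  }
  out <- data.frame(case_id = raw[[colmap$case_id]],
                    activity = raw[[colmap$activity]],
                    stringsAsFactors = FALSE)
  ts <- as_epoch_seconds(raw[[colmap$timestamp]], format = colmap$timestamp_format)
  if (anyNA(ts)) {
    bad <- which(is.na(ts)) + 1L  # +1 for the header line
    stop(sprintf("unparseable timestamp(s) in %s at line(s): %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out$timestamp <- ts
  optional <- c("event_type", "resource", "emergency", "patient_id", "cost")
  for (f in optional) {
    src <- colmap[[f]]
    if (!is.na(src) && src %in% names(raw)) out[[f]] <- raw[[src]]
  }
  extra <- setdiff(names(raw), unlist(colmap[ERLOG_COLUMNS], use.names = FALSE))
  for (nm in extra) out[[nm]] <- raw[[nm]]
  as_erlog(out, on_invalid_emergency = on_invalid_emergency)
}

#' Write an ER event log to CSV
#'
#' Inverse of [read_erlog_csv()]: writing and re-reading reproduces the log
#' field-for-field (timestamps are serialized in ISO 8601 at second
#' precision).
#'
#' @param log an `erlog`.
#' @param path output file path.
#' @param colmap an [er_colmap()] naming the output columns.
#' @return `path`, invisibly.
#' @export
write_erlog_csv <- function(log, path, colmap = er_colmap()) {
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL,
                    a = log$case_id, b = log$activity,
                    c = format_epoch(log$timestamp))
  names(out) <- c(colmap$case_id, colmap$activity, colmap$timestamp)
  put <- function(field, values, fmt = identity) {
    src <- colmap[[field]]
    if (!is.na(src)) out[[src]] <<- fmt(values)
  }
  put("event_type", log$event_type,
      function(x) ifelse(x == "start", "Start", "Complete"))
  put("resource", log$resource)
  put("emergency", log$emergency)
  put("patient_id", log$patient_id)
  if (!all(is.na(log$cost))) put("cost", log$cost)
  extra <- setdiff(names(log), c(ERLOG_COLUMNS, ".start_explicit"))
  for (nm in extra) out[[nm]] <- log[[nm]]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an event log from XES
#'
#' Reads the standard trace/event structure using the `concept:name`,
#' `time:timestamp`, `org:resource` and `lifecycle:transition` keys.
#' Trace-level `concept:name` becomes the case id; trace-level `emergency`
#' and `patient_id`/`pid` attributes are honoured when present.
#'
#' @param path path to an XES file.
#' @return an `erlog`.
#' @export
read_erlog_xes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  traces <- xml2::xml_find_all(doc, ".//trace")
  if (!length(traces)) stop("XES file contains no traces: ", path, call. = FALSE)
  trace_attr <- function(node, key) {
    n <- xml2::xml_find_first(node, sprintf("./*[@key='%s']", key))
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }
  rows <- vector("list", length(traces))
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    cid <- trace_attr(tr, "concept:name")
    if (is.na(cid)) cid <- sprintf("trace_%d", ti)
    pid <- trace_attr(tr, "patient_id")
    if (is.na(pid)) pid <- trace_attr(tr, "pid")
    emer <- trace_attr(tr, "emergency")
    evs <- xml2::xml_find_all(tr, "./event")
    if (!length(evs)) {
      stop(sprintf("XES trace %d ('%s') has no events", ti, cid), call. = FALSE)
    }
    get <- function(key) {
      vapply(evs, function(e) {
        n <- xml2::xml_find_first(e, sprintf("./*[@key='%s']", key))
        if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
      }, character(1))
    }
    act <- get("concept:name")
    ts <- get("time:timestamp")
    if (anyNA(act) || anyNA(ts)) {
      stop(sprintf("XES trace %d ('%s') has events lacking concept:name or time:timestamp",
                   ti, cid), call. = FALSE)
    }
    rows[[ti]] <- data.frame(
      case_id = cid, activity = act,
      timestamp = gsub("T", " ", sub("(\\+|Z).*$", "", ts)),
      event_type = ifelse(is.na(get("lifecycle:transition")), "complete",
                          get("lifecycle:transition")),
      resource = get("org:resource"),
      emergency = emer, patient_id = pid,
      cost = suppressWarnings(as.numeric(get("cost:total"))),
      stringsAsFactors = FALSE)
  }
  as_erlog(do.call(rbind, rows))
}

#' Write an event log to XES
#'
#' @param log an `erlog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_erlog_xes <- function(log, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<log xes.version="1.0">')
  ct <- case_table(log)
  for (k in seq_len(nrow(ct))) {
    cid <- ct$case_id[k]
    w('  <trace>')
    w('    <string key="concept:name" value="%s"/>', esc(cid))
    if (!is.na(ct$patient_id[k])) {
      w('    <string key="patient_id" value="%s"/>', esc(ct$patient_id[k]))
    }
    if (!is.na(ct$emergency[k])) {
      w('    <int key="emergency" value="%d"/>', ct$emergency[k])
    }
    ev <- log[log$case_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      w('    <event>')
      w('      <string key="concept:name" value="%s"/>', esc(ev$activity[i]))
      w('      <date key="time:timestamp" value="%s"/>',
        format_epoch(ev$timestamp[i], "%Y-%m-%dT%H:%M:%S"))
      w('      <string key="lifecycle:transition" value="%s"/>', ev$event_type[i])
      if (!is.na(ev$resource[i])) {
        w('      <string key="org:resource" value="%s"/>', esc(ev$resource[i]))
      }
      if (!is.na(ev$cost[i])) {
        w('      <float key="cost:total" value="%s"/>',
          format(ev$cost[i], scientific = FALSE))
      }
      w('    </event>')
    }
    w('  </trace>')
  }
  w('</log>')
  invisible(path)
}
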