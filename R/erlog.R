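#' @keywords internal
"_PACKAGE"

# Canonical event columns. `timestamp` is numeric seconds since epoch
# (timezone-naive, interpreted as UTC); reports convert to hours/minutes.
ERLOG_COLUMNS <- c("case_id", "activity", "timestamp", "event_type",
                   "resource", "emergency", "patient_id", "cost")

norm_label <- function(x) tolower(trimws(as.character(x)))

#' Construct an ER event log from a data frame of events
#'
#' An `erlog` is a data frame with one row per event and the columns
#' `case_id`, `activity`, `timestamp` (numeric seconds since epoch),
#' `event_type` (`"start"` or `"complete"`), `resource`, `emergency`
#' (KTAS level 1-5 or `NA`; lower is more urgent), `patient_id` and
#' `cost`. Extra columns are preserved as open event attributes. Events
#' are grouped by case (in order of first appearance) and sorted within
#' each case by timestamp; ties keep the original input order.
#'
#' @param events data frame with at least `case_id`, `activity`,
#'   `timestamp`. `timestamp` may be numeric (seconds), `POSIXct`, or
#'   character in ISO 8601.
#' @param on_invalid_emergency `"error"` (default) rejects emergency
#'   values outside 1-5; `"na"` coerces them to missing.
#' @return an object of class `erlog` (a data frame).
#' @examples
#' log <- as_erlog(data.frame(
#'   case_id = c(1, 1, 2), activity = c("Entry", "Treatment", "Entry"),
#'   timestamp = c("2018-02-01 19:05:00", "2018-02-01 19:17:00",
#'                 "2018-02-01 19:21:00")))
#' n_cases(log)
#' @export
as_erlog <- function(events, on_invalid_emergency = c("error", "na")) {
  on_invalid_emergency <- match.arg(on_invalid_emergency)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  mandatory <- c("case_id", "activity", "timestamp")
  missing_cols <- setdiff(mandatory, names(events))
  if (length(missing_cols)) {
    stop("event table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events$case_id <- as.character(events$case_id)
  events$activity <- trimws(as.character(events$activity))
  events$timestamp <- as_epoch_seconds(events$timestamp)
  if (anyNA(events$timestamp)) {
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(which(is.na(events$timestamp)), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(events$event_type)) {
    events$event_type <- rep("complete", nrow(events))
  } else {
    events$event_type <- norm_label(events$event_type)
    events$event_type[is.na(events$event_type) | events$event_type == ""] <- "complete"
    bad <- !events$event_type %in% c("start", "complete")
    if (any(bad)) {
      stop("event_type must be 'start' or 'complete'; offending row(s): ",
           paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(events$resource)) events$resource <- rep(NA_character_, nrow(events))
  events$resource <- as.character(events$resource)
  events$resource[!is.na(events$resource) & trimws(events$resource) == ""] <- NA_character_
  if (is.null(events$emergency)) {
    events$emergency <- rep(NA_integer_, nrow(events))
  } else {
    em <- suppressWarnings(as.integer(events$emergency))
    bad <- !is.na(em) & !(em %in% 1:5)
    bad <- bad | (is.na(em) & !is.na(events$emergency) &
                    trimws(as.character(events$emergency)) != "")
    if (any(bad)) {
      if (on_invalid_emergency == "error") {
        stop("emergency value outside KTAS range 1-5 at row(s): ",
             paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
      }
      em[bad] <- NA_integer_
    }
    events$emergency <- em
  }
  if (is.null(events$patient_id)) events$patient_id <- rep(NA_character_, nrow(events))
  events$patient_id <- as.character(events$patient_id)
  if (is.null(events$cost)) {
    events$cost <- rep(NA_real_, nrow(events))
  } else {
    events$cost <- suppressWarnings(as.numeric(events$cost))
    if (any(events$cost < 0, na.rm = TRUE)) {
      stop("negative cost value(s) in event table", call. = FALSE)
    }
  }
  extra <- setdiff(names(events), ERLOG_COLUMNS)
  events <- events[, c(ERLOG_COLUMNS, extra), drop = FALSE]
  ord <- order(match(events$case_id, unique(events$case_id)),
               events$timestamp, seq_len(nrow(events)), method = "radix")
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- c("erlog", "data.frame")
  events
}

# Parse a timestamp vector to numeric seconds since epoch (UTC, naive).
# `format` is a strptime format; ISO 8601 is auto-detected first because a
# silent day/month swap is the worst possible failure mode for dd/mm data.
as_epoch_seconds <- function(x, format = "%d/%m/%Y %H:%M") {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  iso <- grepl("^\\s*\\d{4}-\\d{2}-\\d{2}", x)
  if (any(iso, na.rm = TRUE)) {
    ix <- which(iso)
    v <- rep(NA_real_, length(ix))
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      todo <- is.na(v)
      if (!any(todo)) break
      v[todo] <- as.numeric(as.POSIXct(strptime(x[ix][todo], fmt, tz = "UTC")))
    }
    out[ix] <- v
  }
  rest <- which(!iso & !is.na(x) & trimws(x) != "")
  if (length(rest)) {
    v <- as.POSIXct(strptime(x[rest], format = format, tz = "UTC"))
    out[rest] <- as.numeric(v)
    # retry with explicit seconds if the stated format dropped them
    still <- rest[is.na(out[rest])]
    if (length(still) && !grepl("%S", format)) {
      v2 <- as.POSIXct(strptime(x[still], format = paste0(format, ":%S"), tz = "UTC"))
      out[still] <- as.numeric(v2)
    }
  }
  out
}

format_epoch <- function(x, format = "%Y-%m-%d %H:%M:%S") {
  format(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"), format, tz = "UTC")
}

#' @export
print.erlog <- function(x, ...) {
  cat(sprintf("ER event log: %d events, %d cases, %d activities\n",
              nrow(x), n_cases(x), length(activities(x))))
  if (nrow(x)) {
    sp <- log_span(x)
    cat(sprintf("span: %s -- %s\n", format_epoch(sp[1]), format_epoch(sp[2])))
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat(sprintf("... and %d more events\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Number of cases in an event log
#' @param log an `erlog`.
#' @return integer count of distinct cases.
#' @export
n_cases <- function(log) length(unique(log$case_id))

#' Activity alphabet of an event log
#' @param log an `erlog`.
#' @return character vector of distinct activity labels, in order of first
#'   appearance.
#' @export
activities <- function(log) unique(log$activity)

#' Time span of an event log
#' @param log an `erlog`.
#' @return numeric length-2 vector (earliest, latest timestamp in seconds).
#' @export
log_span <- function(log) {
  if (!nrow(log)) return(c(NA_real_, NA_real_))
  range(log$timestamp)
}

# Occurrence view: the activity-occurrence timeline of the log. A start
# event that has a later (or simultaneous) complete event for the same
# case and activity is lifecycle metadata and is dropped (its timestamp is
# kept aside as the explicit start of the paired occurrence); an unpaired
# start event stands as an occurrence at its own timestamp. Complete-only
# logs pass through untouched. The returned erlog gains a `.start_explicit`
# column (NA where no explicit start was recorded).
occurrences <- function(log) {
  log$.start_explicit <- rep(NA_real_, nrow(log))
  is_start <- log$event_type == "start"
  if (!any(is_start)) return(log)
  drop <- logical(nrow(log))
  key <- paste(log$case_id, norm_label(log$activity), sep = "\r")
  for (k in unique(key[is_start])) {
    idx <- which(key == k)           # already time-sorted within case
    pending <- integer(0)            # FIFO queue of unmatched start rows
    for (i in idx) {
      if (log$event_type[i] == "start") {
        pending <- c(pending, i)
      } else if (length(pending)) {
        log$.start_explicit[i] <- log$timestamp[pending[1L]]
        drop[pending[1L]] <- TRUE
        pending <- pending[-1L]
      }
    }
  }
  out <- log[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer start times for events and return an interval view
#'
#' In complete-only logs the start time of an event is the complete time of
#' the immediately preceding event in the same case; the first event of a
#' case gets its own complete time (duration zero). Events recorded with an
#' explicit start/complete pair keep the recorded interval.
#'
#' @param log an `erlog`.
#' @return data frame with one row per activity occurrence: `case_id`,
#'   `activity`, `resource`, `start_time`, `complete_time` (numeric
#'   seconds), `duration` (seconds).
#' @export
infer_start_times <- function(log) {
  occ <- occurrences(log)
  n <- nrow(occ)
  if (!n) {
    return(data.frame(case_id = character(0), activity = character(0),
                      resource = character(0), start_time = numeric(0),
                      complete_time = numeric(0), duration = numeric(0)))
  }
  first_of_case <- !duplicated(occ$case_id)
  prev_complete <- c(NA_real_, occ$timestamp[-n])
  start <- ifelse(first_of_case, occ$timestamp, prev_complete)
  explicit <- !is.na(occ$.start_explicit)
  start[explicit] <- occ$.start_explicit[explicit]
  data.frame(case_id = occ$case_id, activity = occ$activity,
             resource = occ$resource, start_time = start,
             complete_time = occ$timestamp,
             duration = occ$timestamp - start,
             stringsAsFactors = FALSE)
}

# Per-case summary used across indicator modules (occurrence view).
case_table <- function(log) {
  occ <- occurrences(log)
  if (!nrow(occ)) {
    return(data.frame(case_id = character(0), patient_id = character(0),
                      emergency = integer(0), first_time = numeric(0),
                      last_time = numeric(0), n_events = integer(0)))
  }
  first <- !duplicated(occ$case_id)
  last <- !duplicated(occ$case_id, fromLast = TRUE)
  data.frame(case_id = occ$case_id[first],
             patient_id = occ$patient_id[first],
             emergency = occ$emergency[first],
             first_time = occ$timestamp[first],
             last_time = occ$timestamp[last],
             n_events = as.integer(tabulate(match(occ$case_id,
                                                  occ$case_id[first]))),
             stringsAsFactors = FALSE)
}

#' Variant of a case
#'
#' The variant of a case is its ordered sequence of activity labels
#' (occurrence view: lifecycle start events paired with a complete are not
#' separate occurrences).
#'
#' @param case an `erlog` containing a single case, or any `erlog` (the
#'   first case is used with a warning if several are present).
#' @return character vector of activity labels.
#' @export
variant_of <- function(case) {
  ids <- unique(case$case_id)
  if (length(ids) > 1L) {
    warning("multiple cases supplied; using the first")
    case <- case[case$case_id == ids[1L], , drop = FALSE]
  }
  occurrences(case)$activity
}

#' Variants of all cases in a log
#' @param log an `erlog`.
#' @param sep separator used to join activity labels (default `" > "`).
#' @return named character vector: one joined variant string per case, named
#'   by `case_id`, in case order.
#' @export
case_variants <- function(log, sep = " > ") {
  occ <- occurrences(log)
  if (!nrow(occ)) return(stats::setNames(character(0), character(0)))
  v <- tapply(occ$activity, factor(occ$case_id, levels = unique(occ$case_id)),
              paste, collapse = sep)
  stats::setNames(as.character(v), names(v))
}

#' Apply a named aggregation function to a sample of measurements
#'
#' The aggregation functions used throughout the indicator framework:
#' average, median, minimum, maximum and standard deviation. The standard
#' deviation is the population form (divide by n) by default.
#'
#' @param values non-empty numeric vector.
#' @param f one of `"avg"`, `"med"`, `"min"`, `"max"`, `"std"`
#'   (case-insensitive).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return a single number.
#' @examples
#' aggregate_samples(c(1, 2, 3, 4), "avg")  # 2.5
#' aggregate_samples(c(1, 2, 3, 4), "std")  # 1.118...
#' @export
aggregate_samples <- function(values, f = c("avg", "med", "min", "max", "std"),
                              sd_type = c("population", "sample")) {
  f <- match.arg(tolower(f[1L]), c("avg", "med", "min", "max", "std"))
  sd_type <- match.arg(sd_type)
  values <- as.numeric(values)
  if (!length(values)) stop("no measurements", call. = FALSE)
  switch(f,
         avg = mean(values),
         med = stats::median(values),
         min = min(values),
         max = max(values),
         std = {
           if (sd_type == "population") {
             sqrt(mean((values - mean(values))^2))
           } else {
             stats::sd(values)
           }
         })
}

# Standard aggregate block reported for every sample-valued indicator.
summarize_samples <- function(values, unit = "seconds", scale = 1) {
  v <- as.numeric(values) / scale
  if (!length(v)) {
    return(list(n = 0L, avg = NA_real_, med = NA_real_,
                min = NA_real_, max = NA_real_, unit = unit))
  }
  list(n = length(v), avg = mean(v), med = stats::median(v),
       min = min(v), max = max(v), unit = unit)
}
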