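# Time-perspective indicators. All samples are returned in seconds as a
# data frame of class "duration_sample" (case_id, seconds, plus context
# columns); reports convert to hours (LOS family) or minutes (cycle-time
# family).

duration_sample <- function(case_id, seconds, ...) {
  out <- data.frame(case_id = as.character(case_id), seconds = seconds,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("duration_sample", "data.frame")
  out
}

#' Length of stay per case
#'
#' One sample per case: time from the case's first to its last activity
#' occurrence. Single-event cases have length of stay zero.
#'
#' @param log an `erlog`.
#' @return a `duration_sample` data frame (`case_id`, `seconds`,
#'   `emergency`, `variant`).
#' @export
los <- function(log) {
  ct <- case_table(log)
  duration_sample(ct$case_id, ct$last_time - ct$first_time,
                  emergency = ct$emergency,
                  variant = unname(case_variants(log)))
}

#' Length of stay restricted to a variant
#'
#' @param log an `erlog`.
#' @param variant either a character vector of activity labels (exact
#'   variant match), or a predicate `function(activities) -> logical`
#'   applied to each case's activity sequence (e.g. terminal-activity
#'   selectors for the hospitalized-vs-discharged split).
#' @return a `duration_sample` for the matching cases (empty if none
#'   match, which is not an error).
#' @export
los_by_variant <- function(log, variant) {
  all_los <- los(log)
  if (is.function(variant)) {
    vs <- strsplit(all_los$variant, " > ", fixed = TRUE)
    keep <- vapply(vs, function(a) isTRUE(variant(a)), logical(1))
  } else {
    target <- paste(variant, collapse = " > ")
    keep <- all_los$variant == target
  }
  out <- all_los[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Selector for cases ending in a given activity
#'
#' Convenience predicate for [los_by_variant()]: selects cases whose final
#' activity matches `label` (case-insensitively), e.g. `"hospitalization"`
#' or `"discharge"`.
#'
#' @param label terminal activity label.
#' @return a predicate function over activity sequences.
#' @export
ends_with_activity <- function(label) {
  lab <- norm_label(label)
  function(acts) length(acts) > 0 && norm_label(acts[length(acts)]) == lab
}

# Named KTAS groupings used in reporting: lower KTAS = more urgent.
KTAS_PRESETS <- list(severe = c(1L, 2L), moderate = 3L, mild = c(4L, 5L))

#' Length of stay restricted to KTAS emergency levels
#'
#' @param log an `erlog`.
#' @param levels non-empty subset of 1:5, or one of the preset names
#'   `"severe"` (KTAS 1-2), `"moderate"` (KTAS 3), `"mild"` (KTAS 4-5).
#' @return a `duration_sample` for cases whose emergency value is in
#'   `levels`; cases with no emergency value are excluded and their count
#'   is attached as attribute `excluded`.
#' @export
los_by_emergency <- function(log, levels) {
  if (is.character(levels)) {
    levels <- KTAS_PRESETS[[match.arg(levels, names(KTAS_PRESETS))]]
  }
  levels <- as.integer(levels)
  if (!length(levels) || !all(levels %in% 1:5)) {
    stop("levels must be a non-empty subset of 1:5 or a preset name",
         call. = FALSE)
  }
  all_los <- los(log)
  out <- all_los[!is.na(all_los$emergency) & all_los$emergency %in% levels, ,
                 drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(is.na(all_los$emergency))
  out
}

# Consecutive-occurrence gaps: helper shared by cycle_time / DFG.
# Returns one row per non-final occurrence: case_id, activity, successor,
# gap (seconds), occ_time.
consecutive_gaps <- function(log) {
  occ <- occurrences(log)
  n <- nrow(occ)
  if (n < 2L) {
    return(data.frame(case_id = character(0), activity = character(0),
                      successor = character(0), gap = numeric(0),
                      occ_time = numeric(0), stringsAsFactors = FALSE))
  }
  same_case <- occ$case_id[-n] == occ$case_id[-1L]
  data.frame(case_id = occ$case_id[-n][same_case],
             activity = occ$activity[-n][same_case],
             successor = occ$activity[-1L][same_case],
             gap = (occ$timestamp[-1L] - occ$timestamp[-n])[same_case],
             occ_time = occ$timestamp[-n][same_case],
             stringsAsFactors = FALSE)
}

#' Cycle time of a clinical activity
#'
#' For every occurrence of `activity` that has a successor within its
#' case, the sample is the elapsed time to that successor. The final
#' occurrence of a case yields no sample.
#'
#' @param log an `erlog`.
#' @param activity activity label (matched case-insensitively).
#' @return a `duration_sample` (`case_id`, `seconds`, `successor`).
#' @export
cycle_time <- function(log, activity) {
  target <- norm_label(activity)
  if (!target %in% norm_label(activities(log))) {
    stop(sprintf("unknown activity '%s'; log contains: %s", activity,
                 paste(activities(log), collapse = ", ")), call. = FALSE)
  }
  g <- consecutive_gaps(log)
  g <- g[norm_label(g$activity) == target, , drop = FALSE]
  duration_sample(g$case_id, g$gap, successor = g$successor)
}

#' Initial response time after arrival at the ER
#'
#' Time from a case's first entry event to its immediate successor (the
#' first clinical service after arrival). Cases without an entry event, or
#' whose entry is the final event, yield no sample and are counted in the
#' `skipped` attribute.
#'
#' @param log an `erlog`.
#' @param entry_label label of the entry activity (default `"entry"`).
#' @return a `duration_sample` with attribute `skipped` (named counts
#'   `no_entry`, `no_successor`).
#' @export
initial_response_time <- function(log, entry_label = "entry") {
  entry <- norm_label(entry_label)
  occ <- occurrences(log)
  n <- nrow(occ)
  ids <- unique(occ$case_id)
  is_entry <- norm_label(occ$activity) == entry
  # index of the first entry occurrence per case that has one
  idx <- which(is_entry)[!duplicated(occ$case_id[is_entry])]
  has_succ <- idx < n & occ$case_id[pmin(idx + 1L, n)] == occ$case_id[idx]
  no_entry <- length(ids) - length(idx)
  no_successor <- sum(!has_succ)
  idx <- idx[has_succ]
  out <- duration_sample(occ$case_id[idx],
                         occ$timestamp[idx + 1L] - occ$timestamp[idx],
                         successor = occ$activity[idx + 1L])
  attr(out, "skipped") <- c(no_entry = no_entry, no_successor = no_successor)
  out
}

#' Door-to-doctor time
#'
#' Per case: timestamp of the first consultation occurrence minus the
#' timestamp of the first entry occurrence. Cases lacking either activity
#' are skipped and counted. `use = "first"` (default) pairs first entry
#' with first consultation; `use = "last"` pairs first entry with the last
#' consultation.
#'
#' @param log an `erlog`.
#' @param entry_label,consultation_label activity labels.
#' @param use `"first"` or `"last"` consultation occurrence.
#' @return a `duration_sample` with attribute `skipped` (count of cases
#'   lacking entry or consultation).
#' @export
door_to_doctor_time <- function(log, entry_label = "entry",
                                consultation_label = "consultation",
                                use = c("first", "last")) {
  use <- match.arg(use)
  occ <- occurrences(log)
  ids <- unique(occ$case_id)
  cid <- factor(occ$case_id, levels = ids)
  act <- norm_label(occ$activity)
  pick <- function(label, fun) {
    sel <- act == norm_label(label)
    v <- rep(NA_real_, length(ids))
    if (any(sel)) {
      t <- tapply(occ$timestamp[sel], cid[sel], fun)
      v[match(names(t), ids)] <- as.numeric(t)
    }
    v
  }
  t_entry <- pick(entry_label, min)
  t_cons <- pick(consultation_label, if (use == "first") min else max)
  ok <- !is.na(t_entry) & !is.na(t_cons)
  out <- duration_sample(ids[ok], t_cons[ok] - t_entry[ok])
  attr(out, "skipped") <- sum(!ok)
  out
}
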