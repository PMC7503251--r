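# Consolidated indicator report: preprocessing followed by every
# computable indicator. Indicators whose required data are absent (cost,
# vitals, reference language) are reported as not computable rather than
# failing the run.

#' Compute the full ER indicator report
#'
#' Runs the preprocessing remedies (collateral deduplication, deletion of
#' time-travel and form-based cases) and then all sixteen indicators of
#' the time / cost / quality / flexibility framework that the log
#' supports. Length-of-stay indicators are reported in hours, cycle-time
#' indicators in minutes.
#'
#' @param log an `erlog` or a path to a CSV event log.
#' @param entry_label,consultation_label activity labels for arrival and
#'   physician consultation.
#' @param hospitalization_label,discharge_label terminal activity labels
#'   for the variant split.
#' @param grid_width bin width in seconds for workload and staffing
#'   profiles (default 1 h).
#' @param revisit_window revisit window in seconds (default 1 day).
#' @param reference optional [stoch_lang()] (or path to a stochastic
#'   language CSV) to compare against with the matching rate.
#' @param triage_rules optional `triage_rules` table (or path to a JSON
#'   rule file) for the triage-accuracy indicator; vitals must be attached
#'   to the log.
#' @param tpr_direction passed to [triage_response_rate()].
#' @param preprocess run the preprocessing remedies first (default TRUE).
#' @param colmap an [er_colmap()] used when `log` is a path.
#' @return an object of class `erppi_report`.
#' @export
erppi_report <- function(log,
                         entry_label = "entry",
                         consultation_label = "consultation",
                         hospitalization_label = "hospitalization",
                         discharge_label = "discharge",
                         grid_width = 3600,
                         revisit_window = 86400,
                         reference = NULL,
                         triage_rules = NULL,
                         tpr_direction = "printed",
                         preprocess = TRUE,
                         colmap = er_colmap()) {
  input <- if (is.character(log)) log else "<in-memory log>"
  if (is.character(log)) log <- read_erlog_csv(log, colmap)
  stopifnot(inherits(log, "erlog"))
  if (is.character(reference)) reference <- read_stoch_lang(reference)
  if (is.character(triage_rules)) triage_rules <- read_triage_rules(triage_rules)

  prep <- list(collateral_removed = 0L, cases_removed = 0L, report = NULL)
  if (preprocess) {
    dd <- deduplicate_collateral(log)
    vitals <- attr(log, "vitals")
    log <- dd$log
    prep$collateral_removed <- dd$removed
    if (norm_label(entry_label) %in% norm_label(activities(log))) {
      rm <- remove_imperfect_cases(log, entry_label)
      log <- rm$log
      prep$cases_removed <- nrow(rm$report)
      prep$report <- rm$report
    }
    attr(log, "vitals") <- vitals
  }

  hours <- 3600; minutes <- 60
  blk <- function(samples, unit, scale, notes = NULL) {
    c(list(status = "ok"), summarize_samples(samples$seconds, unit, scale),
      if (!is.null(notes)) list(notes = notes))
  }
  nc_blk <- function(reason) list(status = "not computable", reason = reason)
  ind <- list()

  ind$ERPPIT1 <- blk(los(log), "hours", hours)
  hos <- los_by_variant(log, ends_with_activity(hospitalization_label))
  dis <- los_by_variant(log, ends_with_activity(discharge_label))
  ind$ERPPIT2 <- list(
    status = "ok",
    hospitalized = summarize_samples(hos$seconds, "hours", hours),
    discharged = summarize_samples(dis$seconds, "hours", hours))
  ind$ERPPIT3 <- list(status = "ok")
  for (g in names(KTAS_PRESETS)) {
    s <- los_by_emergency(log, g)
    ind$ERPPIT3[[g]] <- summarize_samples(s$seconds, "hours", hours)
  }
  ind$ERPPIT4 <- list(status = "ok")
  gaps <- consecutive_gaps(log)  # one pass, sliced per activity
  for (a in sort(activities(log))) {
    s <- gaps$gap[norm_label(gaps$activity) == norm_label(a)]
    if (length(s)) ind$ERPPIT4[[a]] <- summarize_samples(s, "minutes", minutes)
  }
  if (norm_label(entry_label) %in% norm_label(activities(log))) {
    irt <- initial_response_time(log, entry_label)
    ind$ERPPIT5 <- blk(irt, "minutes", minutes,
                       notes = list(skipped = as.list(attr(irt, "skipped"))))
  } else {
    ind$ERPPIT5 <- nc_blk(sprintf("no '%s' activity in log", entry_label))
  }
  if (norm_label(consultation_label) %in% norm_label(activities(log))) {
    dtdt <- door_to_doctor_time(log, entry_label, consultation_label)
    ind$ERPPIT6 <- blk(dtdt, "minutes", minutes,
                       notes = list(skipped = attr(dtdt, "skipped")))
  } else {
    ind$ERPPIT6 <- nc_blk(sprintf("no '%s' activity in log", consultation_label))
  }

  ind$ERPPIC1 <- if (all(is.na(log$cost))) {
    nc_blk("cost-detached log (no cost attribute recorded)")
  } else {
    tc <- total_cost(log)
    c(list(status = "ok"), summarize_samples(tc$cost, "currency", 1),
      list(notes = list(missing_cost_events = attr(tc, "missing_cost_events"))))
  }
  ind$ERPPIC2 <- list(status = "ok", value = originator_count(log),
                      unit = "originators")

  if (n_cases(log) >= 2) {
    ind$ERPPIQ1 <- list(
      status = "ok", value = los_std(log) / hours, unit = "hours",
      hospitalized = if (nrow(hos) >= 2)
        aggregate_samples(hos$seconds, "std") / hours else NA,
      discharged = if (nrow(dis) >= 2)
        aggregate_samples(dis$seconds, "std") / hours else NA)
  } else {
    ind$ERPPIQ1 <- nc_blk("fewer than 2 cases")
  }

  grid <- if (nrow(log)) time_grid_for(log, grid_width) else NULL
  resources <- unique(log$resource[!is.na(log$resource)])
  ind$ERPPIQ2 <- if (!length(resources) || is.null(grid)) {
    nc_blk("no originators recorded")
  } else {
    wl_mean <- vapply(resources, function(r) {
      mean(workload(log, r, grid)$workload)
    }, numeric(1))
    list(status = "ok", value = mean(wl_mean), unit = "open activities",
         n = length(resources),
         per_resource = as.list(stats::setNames(round(wl_mean, 3), resources)))
  }

  ind$ERPPIQ3 <- if (is.null(reference)) {
    nc_blk("no reference model language supplied")
  } else {
    list(status = "ok", value = matching_rate(log_language(log), reference),
         unit = "rate", n = n_cases(log))
  }

  ind$ERPPIQ4 <- if (is.null(attr(log, "vitals"))) {
    nc_blk("no vital features attached to the log")
  } else {
    rules <- if (is.null(triage_rules)) triage_rules_synthetic() else triage_rules
    acc <- triage_accuracy(log, rules)
    list(status = "ok", value = as.numeric(acc), unit = "accuracy",
         n = sum(attr(acc, "confusion")),
         notes = list(excluded = attr(acc, "excluded"),
                      rules = rules$name))
  }

  tpr <- triage_response_rate(log, grid, direction = tpr_direction)
  evaluable <- tpr[!is.na(tpr$rate), , drop = FALSE]
  ind$ERPPIQ5 <- if (!nrow(evaluable)) {
    nc_blk("no period with >= 2 evaluable cases (emergency + second event)")
  } else {
    list(status = "ok", value = mean(evaluable$rate), unit = "rate",
         n = nrow(evaluable),
         notes = list(periods_evaluated = nrow(evaluable),
                      direction = tpr_direction))
  }

  ind$ERPPIQ6 <- if (all(is.na(log$patient_id))) {
    nc_blk("no patient identifiers recorded")
  } else {
    rr <- revisit_rate(log, revisit_window)
    list(status = "ok", value = as.numeric(rr), unit = "rate",
         n = attr(rr, "patients"),
         notes = list(pairs = attr(rr, "pairs"),
                      window_hours = revisit_window / hours))
  }

  dfg <- if (nrow(log)) build_dfg(log) else NULL
  ind$ERPPIF1 <- list(status = "ok", value = variant_count(log),
                      unit = "variants", n = n_cases(log))
  ind$ERPPIF2 <- list(status = "ok",
                      value = if (is.null(dfg)) 0L else relation_count(dfg),
                      unit = "relations")

  structure(list(
    indicators = ind,
    preprocessing = prep,
    provenance = list(input = input, n_cases = n_cases(log),
                      n_events = nrow(log),
                      tool = paste0("erppi ", as.character(utils::packageVersion("erppi"))))),
    class = "erppi_report")
}

#' @export
print.erppi_report <- function(x, ...) {
  cat("ER process performance indicator report\n")
  cat(sprintf("  %d cases, %d events (%d collateral events removed, %d imperfect cases deleted)\n",
              x$provenance$n_cases, x$provenance$n_events,
              x$preprocessing$collateral_removed, x$preprocessing$cases_removed))
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  for (nm in names(x$indicators)) {
    b <- x$indicators[[nm]]
    if (b$status != "ok") {
      cat(sprintf("  %-8s not computable: %s\n", nm, b$reason))
    } else if (!is.null(b$avg)) {
      cat(sprintf("  %-8s avg %s / med %s %s (n=%d)\n", nm, fmt(b$avg),
                  fmt(b$med), b$unit, b$n))
    } else if (!is.null(b$value)) {
      cat(sprintf("  %-8s %s %s\n", nm,
                  ifelse(b$value == round(b$value), format(b$value),
                         sprintf("%.4f", b$value)), b$unit))
    } else {
      cat(sprintf("  %-8s (see summary for per-group values)\n", nm))
    }
  }
  invisible(x)
}

#' @export
summary.erppi_report <- function(object, ...) {
  as.data.frame(object)
}

#' @export
as.data.frame.erppi_report <- function(x, ...) {
  rows <- lapply(names(x$indicators), function(nm) {
    b <- x$indicators[[nm]]
    data.frame(indicator = nm, status = b$status,
               value = if (!is.null(b$value)) b$value
                       else if (!is.null(b$avg)) b$avg else NA_real_,
               n = if (!is.null(b$n)) b$n else NA_integer_,
               unit = if (!is.null(b$unit)) b$unit else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize an indicator report to JSON
#'
#' @param report an [erppi_report()].
#' @param path output file path (or `NULL` to return the JSON string).
#' @return the path (invisibly) or the JSON string.
#' @export
write_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
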