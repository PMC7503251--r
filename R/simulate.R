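# Discrete-event simulator of ER event logs with known ground truth,
# plus injectors for the data-imperfection patterns the preprocessing
# remedies target.

#' The 15 canonical ER activities
#' @return character vector of activity labels.
#' @export
er_activities <- function() {
  c("Entry", "Basic Treatment", "First Aid Treatment", "Other Treatment",
    "Diagnostic Test", "Visual Test", "Consultation", "Cooperation Request",
    "Cooperation Arrival", "Decision on Hospitalization or Discharge",
    "Prescription Request", "Prescription Receiving", "Certificate Issuing",
    "Discharge", "Hospitalization")
}

# Default care pathways over the 15 activities. Lengths average ~14.6
# activities per case (so 30k cases yield ~440k events, the scale of a
# year of tertiary-hospital ER data); 36% of mass ends in hospitalization.
er_pathways_default <- function() {
  P <- function(prob, ...) list(prob = prob, activities = c(...))
  E <- "Entry"; BT <- "Basic Treatment"; FA <- "First Aid Treatment"
  OT <- "Other Treatment"; DT <- "Diagnostic Test"; VT <- "Visual Test"
  CO <- "Consultation"; CR <- "Cooperation Request"; CA <- "Cooperation Arrival"
  DE <- "Decision on Hospitalization or Discharge"; PQ <- "Prescription Request"
  PR <- "Prescription Receiving"; CI <- "Certificate Issuing"
  DI <- "Discharge"; HO <- "Hospitalization"
  list(
    P(0.18, E, BT, CO, DT, BT, CO, PQ, PR, CI, DI),
    P(0.17, E, BT, CO, DT, VT, CO, BT, DT, CO, DE, PQ, PR, DI),
    P(0.15, E, FA, CO, DT, BT, VT, CO, DT, CO, BT, DE, PQ, PR, CI, DI),
    P(0.14, E, OT, CO, DT, VT, BT, CO, DT, VT, CO, BT, CO, DE, PQ, PR, CI, DI),
    P(0.12, E, BT, CO, DT, VT, CO, CR, CA, CO, DT, BT, CO, DE, HO),
    P(0.10, E, FA, CO, DT, BT, VT, CO, DT, CR, CA, CO, BT, DT, CO, DE, HO),
    P(0.08, E, FA, BT, CO, DT, VT, CO, CR, CA, BT, DT, CO, VT, CO, DT, BT, CO, DE, HO),
    P(0.06, E, FA, CO, CR, CA, DT, VT, BT, CO, DT, OT, CO, VT, DT, BT, CO, DT, CO, DE, HO))
}

# Mean service times in seconds (time from the preceding occurrence to the
# activity's completion), exponential by default. Chosen once so the
# default expected LOS is ~5.5 h for discharged and ~11 h for hospitalized
# pathways, the scale reported for tertiary-hospital ER stays.
er_service_times_default <- function() {
  60 * c("Entry" = 10, "Basic Treatment" = 30, "First Aid Treatment" = 20,
         "Other Treatment" = 25, "Diagnostic Test" = 45, "Visual Test" = 30,
         "Consultation" = 25, "Cooperation Request" = 12,
         "Cooperation Arrival" = 62,
         "Decision on Hospitalization or Discharge" = 88,
         "Prescription Request" = 12, "Prescription Receiving" = 20,
         "Certificate Issuing" = 15, "Discharge" = 25, "Hospitalization" = 225)
}

# Day shift 08-20 runs five doctors, night shift 20-08 three: the
# day-peaked staffing profile of a mid-size ER.
er_staffing_default <- function() {
  data.frame(
    resource = c(paste0("DayDoc", 1:5), paste0("NightDoc", 1:3)),
    start_hour = c(rep(8L, 5), rep(20L, 3)),
    end_hour = c(rep(20L, 5), rep(8L, 3)),
    stringsAsFactors = FALSE)
}

# Relative arrival intensity per hour of day (day-peaked census pattern).
er_arrival_rates_default <- function() {
  c(3, 2, 2, 2, 2, 2, 3, 4, 6, 8, 9, 10, 10, 9, 9, 8, 8, 8, 9, 9, 8, 6, 5, 4)
}

# Mean event cost per activity (arbitrary currency units).
er_cost_rates_default <- function() {
  c("Entry" = 20, "Basic Treatment" = 60, "First Aid Treatment" = 45,
    "Other Treatment" = 50, "Diagnostic Test" = 120, "Visual Test" = 150,
    "Consultation" = 80, "Cooperation Request" = 10,
    "Cooperation Arrival" = 30,
    "Decision on Hospitalization or Discharge" = 15,
    "Prescription Request" = 10, "Prescription Receiving" = 35,
    "Certificate Issuing" = 12, "Discharge" = 25, "Hospitalization" = 400)
}

#' Scenario configuration for the ER log simulator
#'
#' Defines the study conditions: arrival process, KTAS case mix, care
#' pathways, service-time distributions, staffing and revisit behaviour.
#'
#' @param n_patients number of patients to simulate.
#' @param seed random seed; one global seed spawns a per-patient sub-seed,
#'   so each patient's draws are reproducible independently of
#'   `n_patients`.
#' @param start_date first day of the simulated horizon (ISO date).
#' @param n_days horizon length in days; arrivals spread uniformly over
#'   days and by `arrival_rates` within the day.
#' @param arrival_rates 24 relative arrival intensities by hour of day.
#' @param ktas_mix probability vector over KTAS levels 1-5 (lower = more
#'   urgent).
#' @param ktas_multipliers per-level service-time multipliers (severe
#'   cases occupy the process longer).
#' @param pathways list of `list(prob, activities)` care pathways over the
#'   activity alphabet; probabilities must sum to 1 and every pathway must
#'   have at least 2 activities.
#' @param service_times named vector of mean service times in seconds.
#' @param service_family `"exponential"` or `"deterministic"`.
#' @param staffing data frame `resource`, `start_hour`, `end_hour`
#'   (shifts may wrap midnight).
#' @param cost_rates named vector of mean event costs, or `NULL` for a
#'   cost-detached log.
#' @param revisit_prob probability that a patient returns for a second
#'   visit.
#' @param revisit_gap_hours length-2 range (hours) of the gap between the
#'   end of the first visit and the start of the revisit.
#' @return a list of class `er_scenario`.
#' @export
er_scenario <- function(n_patients = 1000L,
                        seed = 1L,
                        start_date = "2018-02-01",
                        n_days = max(1L, ceiling(n_patients / 80)),
                        arrival_rates = er_arrival_rates_default(),
                        ktas_mix = c(0.01, 0.07, 0.35, 0.42, 0.15),
                        ktas_multipliers = c(1.5, 1.3, 1.0, 0.8, 0.7),
                        pathways = er_pathways_default(),
                        service_times = er_service_times_default(),
                        service_family = c("exponential", "deterministic"),
                        staffing = er_staffing_default(),
                        cost_rates = er_cost_rates_default(),
                        revisit_prob = 0.004,
                        revisit_gap_hours = c(2, 12)) {
  service_family <- match.arg(service_family)
  fail <- function(field, msg) {
    stop(sprintf("invalid scenario field '%s': %s", field, msg), call. = FALSE)
  }
  if (n_patients < 1) fail("n_patients", "must be >= 1")
  if (length(arrival_rates) != 24 || any(arrival_rates < 0) ||
      sum(arrival_rates) <= 0) {
    fail("arrival_rates", "need 24 non-negative values with positive sum")
  }
  if (length(ktas_mix) != 5 || abs(sum(ktas_mix) - 1) > 1e-9 ||
      any(ktas_mix < 0)) {
    fail("ktas_mix", "need 5 non-negative probabilities summing to 1")
  }
  if (length(ktas_multipliers) != 5 || any(ktas_multipliers <= 0)) {
    fail("ktas_multipliers", "need 5 positive multipliers")
  }
  pp <- vapply(pathways, function(p) p$prob, numeric(1))
  if (abs(sum(pp) - 1) > 1e-9 || any(pp < 0)) {
    fail("pathways", "probabilities must be non-negative and sum to 1")
  }
  acts <- unique(unlist(lapply(pathways, function(p) p$activities)))
  if (any(vapply(pathways, function(p) length(p$activities), integer(1)) < 2)) {
    fail("pathways", "every pathway needs at least 2 activities")
  }
  missing_means <- setdiff(acts, names(service_times))
  if (length(missing_means)) {
    fail("service_times", paste("no mean for:", paste(missing_means, collapse = ", ")))
  }
  if (any(service_times <= 0)) fail("service_times", "means must be positive")
  if (!all(c("resource", "start_hour", "end_hour") %in% names(staffing)) ||
      !nrow(staffing)) {
    fail("staffing", "need columns resource, start_hour, end_hour")
  }
  if (!is.null(cost_rates)) {
    missing_costs <- setdiff(acts, names(cost_rates))
    if (length(missing_costs)) {
      fail("cost_rates", paste("no mean for:", paste(missing_costs, collapse = ", ")))
    }
  }
  if (revisit_prob < 0 || revisit_prob > 1) fail("revisit_prob", "must be in [0,1]")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 start_date = start_date, n_days = as.integer(n_days),
                 arrival_rates = arrival_rates, ktas_mix = ktas_mix,
                 ktas_multipliers = ktas_multipliers, pathways = pathways,
                 service_times = service_times,
                 service_family = service_family, staffing = staffing,
                 cost_rates = cost_rates, revisit_prob = revisit_prob,
                 revisit_gap_hours = revisit_gap_hours),
            class = "er_scenario")
}

# Resources on shift for each hour of day (list of length 24).
on_shift_by_hour <- function(staffing) {
  lapply(0:23, function(h) {
    s <- staffing$start_hour; e <- staffing$end_hour
    on <- ifelse(s < e, h >= s & h < e, h >= s | h < e)
    staffing$resource[on]
  })
}

# Analytic expectations implied by a scenario: the ground truth the
# indicator estimators are validated against.
scenario_ground_truth <- function(config) {
  mults <- config$ktas_multipliers
  mix <- config$ktas_mix
  mult_bar <- sum(mix * mults)
  pp <- vapply(config$pathways, function(p) p$prob, numeric(1))
  means <- config$service_times
  path_sum <- vapply(config$pathways, function(p) {
    sum(means[p$activities[-1L]])
  }, numeric(1))
  exp_los <- mult_bar * sum(pp * path_sum)
  group_los <- vapply(KTAS_PRESETS, function(lv) {
    sum(mix[lv] * mults[lv]) / sum(mix[lv]) * sum(pp * path_sum)
  }, numeric(1))
  terminal <- vapply(config$pathways, function(p) {
    norm_label(p$activities[length(p$activities)])
  }, character(1))
  term_los <- function(lab) {
    sel <- terminal == lab
    if (!any(sel)) return(NA_real_)
    mult_bar * sum(pp[sel] * path_sum[sel]) / sum(pp[sel])
  }
  # expected average cycle time per activity: occurrence-weighted mean of
  # the successor's service mean, scaled by the average multiplier
  num <- stats::setNames(numeric(length(means)), names(means))
  den <- stats::setNames(numeric(length(means)), names(means))
  for (k in seq_along(config$pathways)) {
    a <- config$pathways[[k]]$activities
    n <- length(a)
    for (i in seq_len(n - 1L)) {
      num[a[i]] <- num[a[i]] + pp[k] * means[a[i + 1L]]
      den[a[i]] <- den[a[i]] + pp[k]
    }
  }
  exp_ct <- ifelse(den > 0, mult_bar * num / den, NA_real_)
  exp_irt <- mult_bar *
    sum(pp * vapply(config$pathways, function(p) means[p$activities[2L]],
                    numeric(1)))
  vkey <- vapply(config$pathways, function(p) paste(p$activities, collapse = " > "),
                 character(1))
  variant_probs <- tapply(pp, vkey, sum)
  staffing_per_hour <- vapply(on_shift_by_hour(config$staffing), length,
                              integer(1))
  list(expected_los = exp_los,
       expected_los_by_group = group_los,
       expected_los_hospitalized = term_los("hospitalization"),
       expected_los_discharged = term_los("discharge"),
       expected_cycle_time = exp_ct,
       expected_irt = exp_irt,
       variant_probs = variant_probs,
       staffing_per_hour = staffing_per_hour,
       mean_multiplier = mult_bar)
}

#' Simulate an ER event log with known ground truth
#'
#' Each patient arrives on a uniform day at an hour drawn from the
#' day-profile, receives a KTAS level, follows a sampled care pathway, and
#' accumulates sampled service times; events get on-shift resources and
#' (optionally) costs. A fraction of patients revisits. Timestamps are
#' rounded to whole seconds.
#'
#' @param config an [er_scenario()].
#' @return list with `log` (an `erlog`; all events complete-typed) and
#'   `truth` (analytic expectations: mean length of stay overall, per KTAS
#'   group and per terminal activity; mean cycle time per activity; mean
#'   initial response time; variant probabilities; staffing per hour).
#' @export
simulate_erlog <- function(config = er_scenario()) {
  stopifnot(inherits(config, "er_scenario"))
  truth <- scenario_ground_truth(config)
  origin <- as_epoch_seconds(config$start_date)
  shift <- on_shift_by_hour(config$staffing)
  n <- config$n_patients
  pp <- vapply(config$pathways, function(p) p$prob, numeric(1))
  means <- config$service_times
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  acc <- vector("list", n)
  for (p in seq_len(n)) {
    set.seed(sub_seeds[p])
    pid <- sprintf("P%06d", p)
    day <- sample.int(config$n_days, 1L)
    hour <- sample.int(24L, 1L, prob = config$arrival_rates) - 1L
    arrival <- origin + (day - 1L) * 86400 + hour * 3600 +
      floor(stats::runif(1) * 3600)
    ktas <- sample.int(5L, 1L, prob = config$ktas_mix)
    n_visits <- 1L + (stats::runif(1) < config$revisit_prob)
    gap <- stats::runif(1, config$revisit_gap_hours[1] * 3600,
                        config$revisit_gap_hours[2] * 3600)
    visits <- vector("list", n_visits)
    for (v in seq_len(n_visits)) {
      path <- config$pathways[[sample.int(length(pp), 1L, prob = pp)]]$activities
      len <- length(path)
      mu <- unname(means[path[-1L]]) * config$ktas_multipliers[ktas]
      service <- if (config$service_family == "exponential") {
        stats::rexp(len - 1L, rate = 1 / mu)
      } else {
        mu
      }
      times <- round(arrival + cumsum(c(0, service)))
      hours <- as.integer((times %/% 3600) %% 24)
      res <- vapply(hours, function(h) {
        pool <- shift[[h + 1L]]
        if (!length(pool)) NA_character_
        else if (length(pool) == 1L) pool
        else sample(pool, 1L)
      }, character(1))
      cost <- if (is.null(config$cost_rates)) {
        rep(NA_real_, len)
      } else {
        round(stats::rexp(len, rate = 1 / unname(config$cost_rates[path])), 2)
      }
      visits[[v]] <- data.frame(
        case_id = sprintf("%s_V%d", pid, v), activity = path,
        timestamp = times, event_type = "complete", resource = res,
        emergency = ktas, patient_id = pid, cost = cost,
        stringsAsFactors = FALSE)
      arrival <- times[len] + gap  # start of a potential revisit
    }
    acc[[p]] <- if (n_visits == 1L) visits[[1L]] else rbind(visits[[1L]], visits[[2L]])
  }
  log <- as_erlog(do.call(rbind, acc))
  list(log = log, truth = truth)
}

#' Attach rule-consistent vital features to a simulated log
#'
#' Samples vital signs per case so that `rule_table` classifies them to
#' the case's KTAS level; with probability `noise` the *recorded* level is
#' re-drawn uniformly among the other four levels, forcing a disagreement.
#' The expected triage accuracy is therefore exactly `1 - noise`, which is
#' stored in the returned log's `truth` attribute.
#'
#' @param log an `erlog` with emergency values.
#' @param rule_table a `triage_rules` table; vital sampling supports the
#'   shipped synthetic table (user tables are honoured via
#'   verify-and-retry and may fail for exotic threshold layouts).
#' @param noise disagreement probability in `[0, 1]`.
#' @param seed random seed.
#' @return the log with possibly perturbed `emergency` values, a `vitals`
#'   attribute (data frame `case_id`, `gcs`, `spo2`, `sbp`, `pulse`,
#'   `resp`, `temp`, `pain`, `entry_type`) and a `truth` attribute with
#'   `expected_accuracy`.
#' @export
simulate_vitals <- function(log, rule_table = triage_rules_synthetic(),
                            noise = 0, seed = 1L) {
  stopifnot(noise >= 0, noise <= 1)
  ct <- case_table(log)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  nc <- nrow(ct)
  base <- function(n) data.frame(
    gcs = rep(15L, n), spo2 = round(stats::runif(n, 96, 100), 1),
    sbp = round(stats::runif(n, 105, 155)),
    pulse = round(stats::runif(n, 60, 95)),
    resp = round(stats::runif(n, 12, 18)),
    temp = round(stats::runif(n, 36, 37.5), 1),
    pain = sample(0:3, n, replace = TRUE))
  draw_level <- function(lvl, n) {
    v <- base(n)
    if (lvl == 1L) v$gcs <- sample(3:8, n, replace = TRUE)
    if (lvl == 2L) v$spo2 <- round(stats::runif(n, 86, 89.4), 1)
    if (lvl == 3L) v$pain <- sample(7:10, n, replace = TRUE)
    if (lvl == 4L) v$pain <- sample(4:6, n, replace = TRUE)
    v
  }
  lvl <- ct$emergency
  lvl[is.na(lvl)] <- 5L
  vit <- base(nc)
  for (l in 1:5) {
    sel <- lvl == l
    if (any(sel)) vit[sel, ] <- draw_level(l, sum(sel))
  }
  # verify against the table; re-draw canonical values where needed
  pred <- triage_classify(vit, rule_table)
  bad <- which(pred != lvl)
  for (tries in 1:20) {
    if (!length(bad)) break
    for (l in unique(lvl[bad])) {
      sel <- bad[lvl[bad] == l]
      vit[sel, ] <- draw_level(l, length(sel))
    }
    pred <- triage_classify(vit, rule_table)
    bad <- which(pred != lvl)
  }
  if (length(bad)) {
    stop("could not sample vitals consistent with the rule table for ",
         length(bad), " case(s)", call. = FALSE)
  }
  vit$case_id <- ct$case_id
  vit$entry_type <- sample(c("walk-in", "ambulance", "transfer"), nc,
                           replace = TRUE, prob = c(0.7, 0.25, 0.05))
  vit <- vit[, c("case_id", "gcs", "spo2", "sbp", "pulse", "resp", "temp",
                 "pain", "entry_type")]
  # noise: re-draw the recorded level to disagree with the vitals
  flip <- stats::runif(nc) < noise & !is.na(ct$emergency)
  new_lvl <- ct$emergency
  if (any(flip)) {
    new_lvl[flip] <- vapply(ct$emergency[flip], function(e) {
      sample(setdiff(1:5, e), 1L)
    }, integer(1))
    log$emergency <- new_lvl[match(log$case_id, ct$case_id)]
  }
  attr(log, "vitals") <- vit
  attr(log, "truth") <- list(expected_accuracy = 1 - noise)
  log
}

#' Imperfection-injection configuration
#'
#' @param collateral_dup_rate fraction of events to duplicate in place
#'   ("collateral events").
#' @param time_travel_case_count cases to corrupt with a pre-arrival
#'   timestamp ("inadvertent time travel").
#' @param form_based_case_count cases to corrupt with >= 3 distinct
#'   activities at one instant ("form-based event capture").
#' @param multi_visit_same_day_count patients to give a same-day second
#'   visit recorded under the patient-keyed case id ("exclusive case").
#' @return a list of class `er_imperfections`.
#' @export
er_imperfections <- function(collateral_dup_rate = 0,
                             time_travel_case_count = 0L,
                             form_based_case_count = 0L,
                             multi_visit_same_day_count = 0L) {
  stopifnot(collateral_dup_rate >= 0, collateral_dup_rate <= 1,
            time_travel_case_count >= 0, form_based_case_count >= 0,
            multi_visit_same_day_count >= 0)
  structure(list(collateral_dup_rate = collateral_dup_rate,
                 time_travel_case_count = as.integer(time_travel_case_count),
                 form_based_case_count = as.integer(form_based_case_count),
                 multi_visit_same_day_count = as.integer(multi_visit_same_day_count)),
            class = "er_imperfections")
}

#' Inject data-imperfection patterns into a clean log
#'
#' Injects exactly the patterns the preprocessing remedies target, on
#' disjoint sets of cases, and returns a manifest naming every injected
#' artifact so that round-trip removal can be verified.
#'
#' @param log a clean `erlog`.
#' @param config an [er_imperfections()].
#' @param seed random seed.
#' @param entry_activity entry label used to place time-travel events.
#' @return list with `log` (corrupted `erlog`) and `manifest` (data frame
#'   `case_id`, `pattern` with patterns `time_travel`, `form_based`,
#'   `collateral`, `exclusive_case`).
#' @export
inject_imperfections <- function(log, config, seed = 1L,
                                 entry_activity = "entry") {
  stopifnot(inherits(config, "er_imperfections"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  df <- as.data.frame(log)
  df$.start_explicit <- NULL
  ct <- case_table(log)
  entry <- norm_label(entry_activity)
  manifest <- data.frame(case_id = character(0), pattern = character(0),
                         stringsAsFactors = FALSE)
  used <- character(0)

  pick_cases <- function(eligible, k, what) {
    pool <- setdiff(eligible, used)
    if (length(pool) < k) {
      stop(sprintf("infeasible %s count %d: only %d eligible case(s)",
                   what, k, length(pool)), call. = FALSE)
    }
    chosen <- if (k) sample(pool, k) else character(0)
    used <<- c(used, chosen)
    chosen
  }

  # time travel: move one non-first event strictly before the entry event
  if (config$time_travel_case_count > 0) {
    n_ev <- table(df$case_id)
    eligible <- ct$case_id[ct$case_id %in% names(n_ev)[n_ev >= 2] &
                             !is.na(ct$first_time)]
    has_entry <- tapply(norm_label(df$activity) == entry, df$case_id, any)
    eligible <- eligible[has_entry[eligible]]
    chosen <- pick_cases(eligible, config$time_travel_case_count, "time_travel")
    for (cid in chosen) {
      rows <- which(df$case_id == cid)
      ev_entry <- rows[norm_label(df$activity[rows]) == entry][1L]
      cand <- setdiff(rows, ev_entry)
      i <- if (length(cand) == 1L) cand else sample(cand, 1L)
      df$timestamp[i] <- df$timestamp[ev_entry] -
        round(stats::runif(1, 600, 7200))
    }
    manifest <- rbind(manifest, data.frame(case_id = chosen,
                                           pattern = "time_travel",
                                           stringsAsFactors = FALSE))
  }

  # form-based capture: collapse 3 distinct-activity events onto one instant
  if (config$form_based_case_count > 0) {
    ok <- vapply(split(df$activity, df$case_id), function(a) {
      length(unique(a[-1L])) >= 3L
    }, logical(1))
    eligible <- names(ok)[ok]
    chosen <- pick_cases(eligible, config$form_based_case_count, "form_based")
    for (cid in chosen) {
      rows <- which(df$case_id == cid)[-1L]  # keep the first (entry) event
      acts <- df$activity[rows]
      sel <- rows[!duplicated(acts)][1:3]
      df$timestamp[sel] <- max(df$timestamp[sel])
    }
    manifest <- rbind(manifest, data.frame(case_id = chosen,
                                           pattern = "form_based",
                                           stringsAsFactors = FALSE))
  }

  # exclusive case: a same-day second visit recorded under the same case id
  if (config$multi_visit_same_day_count > 0) {
    single <- names(which(table(ct$patient_id[!is.na(ct$patient_id)]) == 1L))
    eligible <- ct$case_id[!is.na(ct$patient_id) & ct$patient_id %in% single]
    chosen <- pick_cases(eligible, config$multi_visit_same_day_count,
                         "multi_visit_same_day")
    for (cid in chosen) {
      rows <- which(df$case_id == cid)
      clone <- df[rows, , drop = FALSE]
      span <- max(clone$timestamp) - min(clone$timestamp)
      clone$timestamp <- clone$timestamp + span +
        round(stats::runif(1, 1, 3) * 3600)
      df <- rbind(df, clone)
    }
    manifest <- rbind(manifest, data.frame(case_id = chosen,
                                           pattern = "exclusive_case",
                                           stringsAsFactors = FALSE))
  }
  # collateral events: duplicate events whose dedup key is unique, in
  # untouched cases, so the dedup count equals the injected count
  dup_n <- round(config$collateral_dup_rate * nrow(log))  # input log size
  if (dup_n > 0) {
    key <- paste(df$case_id, norm_label(df$activity), df$timestamp,
                 df$event_type, df$resource, sep = "\r")
    unique_key <- !(key %in% key[duplicated(key)])
    cand <- which(unique_key & !(df$case_id %in% used))
    if (length(cand) < dup_n) {
      stop(sprintf("infeasible collateral_dup_rate: need %d unique events, have %d",
                   dup_n, length(cand)), call. = FALSE)
    }
    sel <- if (length(cand) == 1L) cand else sample(cand, dup_n)
    df <- rbind(df, df[sel, , drop = FALSE])
    manifest <- rbind(manifest, data.frame(case_id = df$case_id[sel],
                                           pattern = "collateral",
                                           stringsAsFactors = FALSE))
  }

  rownames(manifest) <- NULL
  list(log = as_erlog(df), manifest = manifest)
}
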