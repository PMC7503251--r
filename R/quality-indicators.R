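#' Standard deviation of the length of stay
#'
#' Population standard deviation of the per-case length of stay; optionally
#' split by a variant selector (e.g. hospitalized vs discharged).
#'
#' @param log an `erlog` with at least two cases.
#' @param variant optional selector passed to [los_by_variant()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return a single number (seconds).
#' @export
los_std <- function(log, variant = NULL, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  samples <- if (is.null(variant)) los(log) else los_by_variant(log, variant)
  if (nrow(samples) < 2L) {
    stop("need at least 2 cases to compute a standard deviation", call. = FALSE)
  }
  aggregate_samples(samples$seconds, "std", sd_type = sd_type)
}

#' Workload series of a resource
#'
#' Per grid bin: events started minus events completed by the resource,
#' cumulated from the second bin onward (the running number of the
#' resource's open activities). Start times follow
#' [infer_start_times()].
#'
#' @param log an `erlog`.
#' @param resource originator label (must occur in the log), or
#'   `"patient_census"` for the fallback mode that uses the number of
#'   patients present in the ER (the `patient_count` series of
#'   [resources_per_period()]) as the workload proxy.
#' @param grid a [time_grid()].
#' @return a data frame of class `workload_series`: `period_start`,
#'   `started`, `completed`, `workload`.
#' @export
workload <- function(log, resource, grid) {
  if (identical(resource, "patient_census")) {
    rp <- resources_per_period(log, grid)
    out <- data.frame(period_start = grid$starts, started = NA_integer_,
                      completed = NA_integer_, workload = rp$patient_count)
    class(out) <- c("workload_series", "data.frame")
    return(out)
  }
  known <- unique(log$resource[!is.na(log$resource)])
  if (!norm_label(resource) %in% norm_label(known)) {
    stop(sprintf("unknown resource '%s'", resource), call. = FALSE)
  }
  iv <- infer_start_times(log)
  iv <- iv[!is.na(iv$resource) & norm_label(iv$resource) == norm_label(resource), ,
           drop = FALSE]
  sb <- bin_of(iv$start_time, grid)
  cb <- bin_of(iv$complete_time, grid)
  started <- tabulate(sb[!is.na(sb)], nbins = grid$n)
  completed <- tabulate(cb[!is.na(cb)], nbins = grid$n)
  out <- data.frame(period_start = grid$starts, started = started,
                    completed = completed,
                    workload = cumsum(started - completed))
  class(out) <- c("workload_series", "data.frame")
  out
}

# ---- stochastic languages and the earth-mover's matching rate ----------

#' Construct a stochastic trace language
#'
#' A stochastic language assigns a probability to each trace variant.
#'
#' @param variants list of character vectors (activity sequences) or a
#'   character vector of variants joined by `">"` / `" > "`.
#' @param p numeric probabilities (non-negative, summing to 1 within
#'   1e-9).
#' @return an object of class `stoch_lang` with elements `variants` (list
#'   of character vectors) and `p`.
#' @export
stoch_lang <- function(variants, p) {
  if (is.character(variants)) {
    variants <- lapply(strsplit(variants, ">", fixed = TRUE), trimws)
  }
  p <- as.numeric(p)
  if (length(variants) != length(p)) {
    stop("variants and p must have equal length", call. = FALSE)
  }
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("probabilities must sum to 1 (got %.12f)", sum(p)),
         call. = FALSE)
  }
  keys <- vapply(variants, paste, character(1), collapse = "\r")
  if (anyDuplicated(keys)) stop("variants must be distinct", call. = FALSE)
  structure(list(variants = variants, p = p), class = "stoch_lang")
}

#' @export
print.stoch_lang <- function(x, ...) {
  cat(sprintf("stochastic language: %d variants\n", length(x$p)))
  v <- vapply(x$variants, paste, character(1), collapse = " > ")
  for (i in utils::head(order(-x$p), 10L)) {
    cat(sprintf("  %.4f  %s\n", x$p[i], v[i]))
  }
  if (length(x$p) > 10L) cat(sprintf("  ... and %d more\n", length(x$p) - 10L))
  invisible(x)
}

#' Stochastic language of an event log
#'
#' The probability of a variant is its case count divided by the number of
#' cases.
#'
#' @param log a non-empty `erlog`.
#' @return a [stoch_lang()].
#' @export
log_language <- function(log) {
  if (!nrow(log)) stop("empty log has no language", call. = FALSE)
  cv <- case_variants(log)
  tab <- table(cv)
  stoch_lang(names(tab), as.numeric(tab) / length(cv))
}

#' Read / write a stochastic language CSV
#'
#' File format: columns `variant` (activities joined by `">"`) and
#' `probability`.
#'
#' @param path file path.
#' @return [read_stoch_lang()] returns a `stoch_lang`;
#'   [write_stoch_lang()] returns `path` invisibly.
#' @export
read_stoch_lang <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "probability") %in% names(df))) {
    stop("stochastic language file needs columns 'variant' and 'probability'",
         call. = FALSE)
  }
  stoch_lang(df$variant, df$probability)
}

#' @param lang a `stoch_lang`.
#' @rdname read_stoch_lang
#' @export
write_stoch_lang <- function(lang, path) {
  utils::write.csv(
    data.frame(variant = vapply(lang$variants, paste, character(1),
                                collapse = " > "),
               probability = lang$p),
    path, row.names = FALSE)
  invisible(path)
}

# Normalized Levenshtein distance matrix between two lists of activity
# sequences: edit distance on label sequences divided by the longer length
# (0 for two empty sequences), so every entry lies in [0, 1]. Labels are
# encoded as single characters so utils::adist does the edit distance.
normalized_levenshtein <- function(va, vb) {
  labels <- unique(c(unlist(va), unlist(vb)))
  # encode each label as one unicode character (offset past ASCII)
  enc <- function(v) {
    vapply(v, function(a) {
      if (!length(a)) return("")
      intToUtf8(match(a, labels) + 255L)
    }, character(1))
  }
  d <- utils::adist(enc(va), enc(vb))
  la <- lengths(va); lb <- lengths(vb)
  denom <- outer(la, lb, pmax)
  denom[denom == 0] <- 1
  d / denom
}

#' Earth-mover's matching rate between two stochastic languages
#'
#' Solves the transportation problem that moves the probability mass of
#' the log language onto the reference model language at minimal cost,
#' where the ground distance between two variants is the normalized
#' Levenshtein distance of their activity sequences (in `[0, 1]`). The
#' matching rate is one minus the optimal transport cost, so it lies in
#' `[0, 1]`, equals 1 iff the languages are identical, and is symmetric in
#' its arguments.
#'
#' @param log_lang,model_lang [stoch_lang()] objects (an `erlog` is
#'   accepted for `log_lang` and converted via [log_language()]).
#' @param distance optional ground-distance function
#'   `function(variants_a, variants_b) -> matrix`; defaults to normalized
#'   Levenshtein.
#' @return a single number in `[0, 1]`.
#' @examples
#' a <- stoch_lang(list(c("a", "b")), 1)
#' b <- stoch_lang(list(c("a", "c")), 1)
#' matching_rate(a, b)  # 0.5
#' @export
matching_rate <- function(log_lang, model_lang, distance = NULL) {
  if (inherits(log_lang, "erlog")) log_lang <- log_language(log_lang)
  if (inherits(model_lang, "erlog")) model_lang <- log_language(model_lang)
  stopifnot(inherits(log_lang, "stoch_lang"), inherits(model_lang, "stoch_lang"))
  if (is.null(distance)) distance <- normalized_levenshtein
  cost <- distance(log_lang$variants, model_lang$variants)
  plan <- transport_plan(log_lang$p, model_lang$p, cost)
  1 - plan$cost
}

# Minimum-cost transportation plan by successive shortest augmenting paths
# on the bipartite residual graph (Bellman-Ford label correction; ground
# costs are non-negative, reduced costs on backward arcs may be negative).
# Supplies and demands must balance. Returns list(flow = matrix, cost).
transport_plan <- function(supply, demand, cost, tol = 1e-12) {
  n <- length(supply); m <- length(demand)
  stopifnot(nrow(cost) == n, ncol(cost) == m)
  if (abs(sum(supply) - sum(demand)) > 1e-9) {
    stop("supply and demand totals differ", call. = FALSE)
  }
  flow <- matrix(0, n, m)
  s_rem <- as.numeric(supply); d_rem <- as.numeric(demand)
  repeat {
    src <- which(s_rem > tol)
    if (!length(src)) break
    # shortest path distances over nodes 1..n (rows), n+1..n+m (cols)
    dist <- rep(Inf, n + m); prev <- rep(0L, n + m)
    dist[src] <- 0
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        if (!is.finite(dist[i])) next
        nd <- dist[i] + cost[i, ]
        upd <- which(nd < dist[n + seq_len(m)] - tol)
        if (length(upd)) {
          dist[n + upd] <- nd[upd]; prev[n + upd] <- i; changed <- TRUE
        }
      }
      for (j in seq_len(m)) {
        if (!is.finite(dist[n + j])) next
        back <- which(flow[, j] > tol)
        if (length(back)) {
          nd <- dist[n + j] - cost[back, j]
          upd <- which(nd < dist[back] - tol)
          if (length(upd)) {
            dist[back[upd]] <- nd[upd]; prev[back[upd]] <- n + j; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    sink <- which(d_rem > tol)
    sink <- sink[is.finite(dist[n + sink])]
    if (!length(sink)) stop("transportation problem infeasible", call. = FALSE)
    j_end <- sink[which.min(dist[n + sink])]
    # reconstruct path and find bottleneck
    path <- integer(0)  # node sequence from end back to a source row
    node <- n + j_end
    while (node != 0L) {
      path <- c(node, path)
      if (node <= n && s_rem[node] > tol && prev[node] == 0L) break
      node <- prev[node]
    }
    delta <- min(s_rem[path[1L]], d_rem[j_end])
    if (length(path) > 2L) {
      for (k in seq(2L, length(path) - 1L)) {
        if (path[k] > n) next
        # backward arc col -> row carries flow[row, col]
        delta <- min(delta, flow[path[k], path[k - 1L] - n])
      }
    }
    for (k in seq(1L, length(path) - 1L)) {
      a <- path[k]; b <- path[k + 1L]
      if (a <= n) flow[a, b - n] <- flow[a, b - n] + delta
      else flow[b, a - n] <- flow[b, a - n] - delta
    }
    s_rem[path[1L]] <- s_rem[path[1L]] - delta
    d_rem[j_end] <- d_rem[j_end] - delta
  }
  list(flow = flow, cost = sum(flow * cost))
}

# ---- triage quality ----------------------------------------------------

#' Synthetic default triage rule table
#'
#' A deterministic most-urgent-first rule table over vital signs, shipped
#' so the triage-accuracy machinery is testable end-to-end. It is a
#' clearly-labelled synthetic placeholder, not the Korean Ministry of
#' Health and Welfare KTAS decision rule (which is not publicly printed);
#' supply your own table via [read_triage_rules()] for real assessments.
#'
#' Structure: a list with `levels`, a named list (`"1"`..`"4"`) of
#' condition lists; each condition is `list(feature, op, value)` with `op`
#' in `le`, `lt`, `ge`, `gt`. Levels are evaluated from 1 (most urgent)
#' upward; the first level with any matching condition is assigned, else 5.
#'
#' @return a list of class `triage_rules`.
#' @export
triage_rules_synthetic <- function() {
  cond <- function(feature, op, value) list(feature = feature, op = op, value = value)
  structure(list(
    name = "synthetic placeholder rules (not the Ministry of Health and Welfare table)",
    levels = list(
      "1" = list(cond("gcs", "le", 8), cond("spo2", "lt", 85), cond("sbp", "lt", 70)),
      "2" = list(cond("gcs", "le", 12), cond("spo2", "lt", 90), cond("sbp", "lt", 90),
                 cond("sbp", "gt", 220), cond("pulse", "gt", 140),
                 cond("resp", "gt", 35), cond("temp", "gt", 41)),
      "3" = list(cond("gcs", "le", 14), cond("spo2", "lt", 94), cond("sbp", "lt", 100),
                 cond("sbp", "gt", 180), cond("pulse", "gt", 120), cond("pulse", "lt", 45),
                 cond("resp", "gt", 28), cond("resp", "lt", 8), cond("temp", "gt", 39),
                 cond("temp", "lt", 35), cond("pain", "ge", 7)),
      "4" = list(cond("pain", "ge", 4), cond("temp", "gt", 38), cond("pulse", "gt", 100),
                 cond("sbp", "gt", 160), cond("resp", "gt", 20))
    )), class = "triage_rules")
}

#' Read / write a triage rule table as JSON
#'
#' @param path file path.
#' @return [read_triage_rules()] returns a `triage_rules` list;
#'   [write_triage_rules()] returns `path` invisibly.
#' @export
read_triage_rules <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = FALSE)
  x$levels <- lapply(x$levels, function(lv) {
    lapply(lv, function(cn) {
      list(feature = cn$feature, op = cn$op, value = as.numeric(cn$value))
    })
  })
  structure(x, class = "triage_rules")
}

#' @param rules a `triage_rules` list.
#' @rdname read_triage_rules
#' @export
write_triage_rules <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Classify KTAS levels from vital features with a rule table
#'
#' @param vitals data frame with (any of) columns `gcs`, `spo2`, `sbp`,
#'   `pulse`, `resp`, `temp`, `pain`; missing features never match a
#'   condition.
#' @param rules a `triage_rules` table (default: the synthetic placeholder
#'   [triage_rules_synthetic()]).
#' @return integer vector of KTAS levels 1-5, one per row.
#' @export
triage_classify <- function(vitals, rules = triage_rules_synthetic()) {
  n <- nrow(vitals)
  out <- rep(5L, n)
  assigned <- rep(FALSE, n)
  for (lvl in as.character(1:4)) {
    conds <- rules$levels[[lvl]]
    if (is.null(conds)) next
    hit <- rep(FALSE, n)
    for (cn in conds) {
      v <- vitals[[cn$feature]]
      if (is.null(v)) next
      h <- switch(cn$op,
                  le = v <= cn$value, lt = v < cn$value,
                  ge = v >= cn$value, gt = v > cn$value,
                  stop("unknown op: ", cn$op, call. = FALSE))
      hit <- hit | (!is.na(h) & h)
    }
    sel <- hit & !assigned
    out[sel] <- as.integer(lvl)
    assigned <- assigned | hit
  }
  out
}

#' Accuracy of medical triage
#'
#' Fraction of cases for which a classifier applied to the case's vital
#' features reproduces the recorded KTAS emergency value. Cases lacking
#' a recorded level or vital features are excluded and counted.
#'
#' @param log an `erlog` whose `vitals` attribute is a data frame with a
#'   `case_id` column plus vital-feature columns (as attached by
#'   [simulate_vitals()]), or pass `vitals` explicitly.
#' @param classifier a function `vitals data frame -> integer levels`, or
#'   a `triage_rules` table (classified via [triage_classify()]).
#' @param vitals optional vitals data frame overriding the attribute.
#' @return the accuracy in `[0, 1]`, with attributes `confusion` (5x5
#'   table, recorded x classified) and `excluded` (count).
#' @export
triage_accuracy <- function(log, classifier = triage_rules_synthetic(),
                            vitals = NULL) {
  if (is.null(vitals)) vitals <- attr(log, "vitals")
  if (is.null(vitals)) stop("no vital features available", call. = FALSE)
  ct <- case_table(log)
  m <- match(ct$case_id, vitals$case_id)
  ok <- !is.na(ct$emergency) & !is.na(m)
  if (!any(ok)) stop("no evaluable cases for triage accuracy", call. = FALSE)
  v <- vitals[m[ok], , drop = FALSE]
  pred <- if (inherits(classifier, "triage_rules")) {
    triage_classify(v, classifier)
  } else {
    as.integer(classifier(v))
  }
  recorded <- ct$emergency[ok]
  acc <- mean(pred == recorded)
  conf <- table(factor(recorded, levels = 1:5), factor(pred, levels = 1:5))
  structure(acc, confusion = conf, excluded = sum(!ok))
}

#' Triage-based patient response rate
#'
#' Cases (with a recorded emergency value and at least two activity
#' occurrences) are ordered by the completion time of their first event.
#' For each consecutive pair whose second-event times both fall in a grid
#' period, the pair is a violation iff the earlier-arriving case got its
#' second event later AND the emergency comparison holds; the period's
#' rate is `1 - violations / (n_period - 1)` where `n_period` counts the
#' period's evaluable cases. Periods with fewer than two evaluable cases
#' are reported as `NA`.
#'
#' With `direction = "printed"` (default) a violation requires the earlier
#' case to have the numerically larger KTAS value (it was less urgent yet
#' also served later); `direction = "urgency"` flips the comparison so
#' that a violation means a more urgent earlier arrival was overtaken.
#'
#' @param log an `erlog`.
#' @param grid a [time_grid()], or `NULL` for a single period spanning the
#'   whole log.
#' @param direction `"printed"` or `"urgency"`.
#' @return data frame: `period_start`, `n`, `violations`, `rate`.
#' @export
triage_response_rate <- function(log, grid = NULL,
                                 direction = c("printed", "urgency")) {
  direction <- match.arg(direction)
  occ <- occurrences(log)
  ids <- unique(occ$case_id)
  cid <- factor(occ$case_id, levels = ids)
  idx <- seq_len(nrow(occ))
  first_i <- idx[!duplicated(cid)]
  second_i <- idx[!duplicated(cid)] + 1L
  has2 <- second_i <= nrow(occ) & occ$case_id[pmin(second_i, nrow(occ))] == ids
  ct <- data.frame(case_id = ids,
                   t1 = occ$timestamp[first_i],
                   t2 = ifelse(has2, occ$timestamp[pmin(second_i, nrow(occ))], NA_real_),
                   emergency = occ$emergency[first_i],
                   stringsAsFactors = FALSE)
  ct <- ct[!is.na(ct$t2) & !is.na(ct$emergency), , drop = FALSE]
  ct <- ct[order(ct$t1, method = "radix"), , drop = FALSE]
  if (is.null(grid)) {
    if (nrow(ct) < 2L) {
      return(data.frame(period_start = NA_real_, n = nrow(ct),
                        violations = NA_integer_, rate = NA_real_))
    }
    grid <- time_grid(min(ct$t2), max(ct$t2) - min(ct$t2) + 1, 1L)
  }
  nc <- nrow(ct)
  later2 <- ct$t2[-nc] > ct$t2[-1L]
  emcmp <- if (direction == "printed") {
    ct$emergency[-nc] > ct$emergency[-1L]
  } else {
    ct$emergency[-nc] < ct$emergency[-1L]
  }
  bins <- bin_of(ct$t2, grid)
  out <- data.frame(period_start = grid$starts, n = 0L,
                    violations = NA_integer_, rate = NA_real_)
  n_per <- tabulate(bins[!is.na(bins)], nbins = grid$n)
  out$n <- n_per
  pair_bin <- ifelse(!is.na(bins[-nc]) & !is.na(bins[-1L]) &
                       bins[-nc] == bins[-1L], bins[-nc], NA_integer_)
  viol <- later2 & emcmp & !is.na(pair_bin)
  viol_per <- tabulate(pair_bin[viol], nbins = grid$n)
  ok <- n_per >= 2L
  out$violations[ok] <- viol_per[ok]
  out$rate[ok] <- 1 - viol_per[ok] / (n_per[ok] - 1L)
  out
}

#' Revisit rate for patients within a time window
#'
#' Counts ordered pairs of cases of the same patient where the later case
#' starts within `window` seconds of the end of the earlier case
#' (boundary inclusive), divided by the number of distinct patients.
#' `mode = "start_to_start"` measures the gap between case start times
#' instead.
#'
#' @param log an `erlog` with patient ids.
#' @param window window in seconds (default 1 day, the same-day revisit
#'   convention).
#' @param mode `"end_to_start"` (default: a revisit means returning after
#'   leaving) or `"start_to_start"`.
#' @return rate in `[0, 1]` with attributes `pairs` and `patients`.
#' @export
revisit_rate <- function(log, window = 86400,
                         mode = c("end_to_start", "start_to_start")) {
  mode <- match.arg(mode)
  stopifnot(window > 0)
  ct <- case_table(log)
  ct <- ct[!is.na(ct$patient_id), , drop = FALSE]
  patients <- unique(ct$patient_id)
  if (!length(patients)) {
    return(structure(0, pairs = 0L, patients = 0L))
  }
  ct <- ct[order(ct$first_time, method = "radix"), , drop = FALSE]
  pairs <- 0L
  multi <- names(which(table(ct$patient_id) > 1L))
  for (p in multi) {
    sub <- ct[ct$patient_id == p, , drop = FALSE]
    nk <- nrow(sub)
    for (k in seq_len(nk - 1L)) {
      ref <- if (mode == "end_to_start") sub$last_time[k] else sub$first_time[k]
      pairs <- pairs + sum(sub$first_time[(k + 1L):nk] - ref <= window)
    }
  }
  structure(pairs / length(patients), pairs = pairs,
            patients = length(patients))
}
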