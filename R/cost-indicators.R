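#' Half-open time grid over a log span
#'
#' Bins are left-closed, right-open: `[origin + (j-1) w, origin + j w)`;
#' an instant exactly on a boundary belongs to the later bin.
#'
#' @param origin start instant of the first bin (numeric seconds, POSIXct
#'   or ISO 8601 character).
#' @param width bin width in seconds (e.g. `3600` for hourly bins).
#' @param n number of bins.
#' @return a list of class `time_grid` with `origin`, `width`, `n`,
#'   `starts`.
#' @export
time_grid <- function(origin, width, n) {
  origin <- as_epoch_seconds(origin)
  stopifnot(length(origin) == 1L, !is.na(origin), width > 0, n >= 1)
  n <- as.integer(n)
  structure(list(origin = origin, width = as.numeric(width), n = n,
                 starts = origin + (seq_len(n) - 1L) * as.numeric(width)),
            class = "time_grid")
}

#' Time grid covering an event log
#'
#' Builds a [time_grid()] whose bins cover the whole span of the log,
#' with the origin aligned down to a multiple of `width` (so hourly grids
#' start on the hour).
#'
#' @param log an `erlog`.
#' @param width bin width in seconds (default 3600 = 1 h).
#' @return a `time_grid`.
#' @export
time_grid_for <- function(log, width = 3600) {
  sp <- log_span(log)
  if (anyNA(sp)) stop("empty log has no span", call. = FALSE)
  origin <- floor(sp[1] / width) * width
  n <- max(1L, as.integer(floor((sp[2] - origin) / width)) + 1L)
  time_grid(origin, width, n)
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: %d bins of %gs from %s\n", x$n, x$width,
              format_epoch(x$origin)))
  invisible(x)
}

# Bin index of an instant (NA outside the grid).
bin_of <- function(t, grid) {
  j <- floor((t - grid$origin) / grid$width) + 1
  j[j < 1 | j > grid$n] <- NA_integer_
  as.integer(j)
}

#' Total cost per case
#'
#' Sums event costs within each case. Events with no recorded cost
#' contribute zero and are counted in the `missing_cost_events` attribute.
#' A log with no cost information at all ("cost-detached") is an error:
#' use [originator_count()] as the indirect cost indicator instead.
#'
#' @param log an `erlog`.
#' @return data frame (`case_id`, `cost`) with attribute
#'   `missing_cost_events`.
#' @export
total_cost <- function(log) {
  if (all(is.na(log$cost))) {
    stop("cost-detached log; use originator_count", call. = FALSE)
  }
  cid <- factor(log$case_id, levels = unique(log$case_id))
  cost <- ifelse(is.na(log$cost), 0, log$cost)
  out <- data.frame(case_id = levels(cid),
                    cost = as.numeric(rowsum(cost, cid, reorder = FALSE)),
                    stringsAsFactors = FALSE)
  attr(out, "missing_cost_events") <- sum(is.na(log$cost))
  out
}

#' Total number of originators
#'
#' Number of distinct resources over all events; events with no originator
#' are ignored. Under the assumption that all resources are full-time
#' workers this is the indirect cost indicator for cost-detached logs.
#'
#' @param log an `erlog`.
#' @return integer count.
#' @export
originator_count <- function(log) {
  length(unique(log$resource[!is.na(log$resource)]))
}

#' Resources and patients present per time period
#'
#' For each grid bin, counts the distinct originators with at least one
#' event interval (see [infer_start_times()]) overlapping the bin, and the
#' number of cases whose first-to-last interval overlaps the bin (the
#' per-hour staffing/census profile).
#'
#' @param log an `erlog`.
#' @param grid a [time_grid()] covering the log span.
#' @param resource_filter optional character vector restricting the
#'   resource count to the given originators.
#' @return data frame: `period_start` (seconds), `resource_count`,
#'   `patient_count`.
#' @export
resources_per_period <- function(log, grid, resource_filter = NULL) {
  res_count <- integer(grid$n)
  pat_count <- integer(grid$n)
  if (nrow(log)) {
    iv <- infer_start_times(log)
    if (!is.null(resource_filter)) {
      iv <- iv[!is.na(iv$resource) &
                 norm_label(iv$resource) %in% norm_label(resource_filter), ,
               drop = FALSE]
    } else {
      iv <- iv[!is.na(iv$resource), , drop = FALSE]
    }
    res_count <- overlap_distinct(iv$start_time, iv$complete_time,
                                  iv$resource, grid)
    ct <- case_table(log)
    pat_count <- overlap_distinct(ct$first_time, ct$last_time, ct$case_id, grid)
  }
  data.frame(period_start = grid$starts, resource_count = res_count,
             patient_count = pat_count)
}

# Count distinct `who` per bin among intervals [s, c] overlapping each
# half-open bin: overlap iff s < bin_end && c >= bin_start.
overlap_distinct <- function(s, cmpl, who, grid) {
  out <- integer(grid$n)
  if (!length(s)) return(out)
  first_bin <- pmax(1L, pmin(grid$n, as.integer(floor((s - grid$origin) / grid$width)) + 1L))
  last_bin <- pmax(1L, pmin(grid$n, as.integer(floor((cmpl - grid$origin) / grid$width)) + 1L))
  # drop intervals entirely outside the grid
  inside <- cmpl >= grid$origin & s < grid$origin + grid$n * grid$width
  first_bin <- first_bin[inside]; last_bin <- last_bin[inside]
  who <- who[inside]
  if (!length(who)) return(out)
  len <- last_bin - first_bin + 1L
  bins <- sequence(len) - 1L + rep(first_bin, len)
  whos <- rep(who, len)
  u <- !duplicated(paste0(bins, "\r", whos))
  tab <- tabulate(bins[u], nbins = grid$n)
  as.integer(tab)
}
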