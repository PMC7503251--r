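#' Build a directly-follows graph with performance annotations
#'
#' For every consecutive pair of activity occurrences within a case, the
#' edge (predecessor, successor) gains one observation and records the
#' time gap; per-edge average and median durations support model-based
#' performance analysis.
#'
#' @param log a non-empty `erlog`.
#' @return an object of class `dfg`: list with `nodes` (activity labels)
#'   and `edges` (data frame `from`, `to`, `frequency`, `avg_duration`,
#'   `med_duration` in seconds).
#' @export
build_dfg <- function(log) {
  if (!nrow(log)) stop("cannot build a DFG from an empty log", call. = FALSE)
  g <- consecutive_gaps(log)
  if (!nrow(g)) {
    edges <- data.frame(from = character(0), to = character(0),
                        frequency = integer(0), avg_duration = numeric(0),
                        med_duration = numeric(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(g$activity, g$successor, sep = "\r")
    uk <- unique(key)
    f <- factor(key, levels = uk)
    parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
    edges <- data.frame(from = parts[, 1L], to = parts[, 2L],
                        frequency = as.integer(tabulate(f, nbins = length(uk))),
                        avg_duration = as.numeric(tapply(g$gap, f, mean)),
                        med_duration = as.numeric(tapply(g$gap, f, stats::median)),
                        stringsAsFactors = FALSE)
    ord <- order(-edges$frequency, edges$from, edges$to, method = "radix")
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = activities(log), edges = edges), class = "dfg")
}

#' @export
print.dfg <- function(x, ...) {
  cat(sprintf("directly-follows graph: %d activities, %d relations\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    show <- utils::head(x$edges, 10L)
    show$avg_duration <- sprintf("%.1f min", show$avg_duration / 60)
    show$med_duration <- sprintf("%.1f min", show$med_duration / 60)
    print(show)
    if (nrow(x$edges) > 10L) cat(sprintf("... and %d more relations\n",
                                         nrow(x$edges) - 10L))
  }
  invisible(x)
}

#' Total number of directly-follows relations
#'
#' @param dfg a [build_dfg()] object.
#' @param top_frac optionally keep only the most frequent edges covering
#'   this fraction of the ranked edge list before counting (display-style
#'   frequency filtering); default 1 = no filtering, the canonical value.
#' @return integer count of distinct edges with frequency >= 1.
#' @export
relation_count <- function(dfg, top_frac = 1) {
  stopifnot(inherits(dfg, "dfg"), top_frac > 0, top_frac <= 1)
  n <- nrow(dfg$edges)
  if (top_frac >= 1) return(n)
  max(0L, as.integer(ceiling(n * top_frac)))
}

#' Total number of variants in a log
#'
#' @param log an `erlog`.
#' @return integer count of distinct case variants.
#' @export
variant_count <- function(log) {
  if (!nrow(log)) return(0L)
  length(unique(case_variants(log)))
}

#' Dotted-chart point data
#'
#' One point per event: the case's rank by first-event time (y), the event
#' timestamp (x) and a colour key. With `color_by = "emergency"` the key
#' follows the urgency-group convention (severe / moderate / mild /
#' unknown).
#'
#' @param log an `erlog`.
#' @param color_by one of `"emergency"`, `"variant"`, `"activity"`.
#' @return data frame: `case_id`, `case_rank`, `timestamp`, `color`.
#' @export
dotted_chart_data <- function(log, color_by = c("emergency", "variant",
                                                "activity")) {
  color_by <- match.arg(color_by)
  if (!nrow(log)) {
    return(data.frame(case_id = character(0), case_rank = integer(0),
                      timestamp = numeric(0), color = character(0),
                      stringsAsFactors = FALSE))
  }
  ct <- case_table(log)
  rank <- rank(ct$first_time, ties.method = "first")
  m <- match(log$case_id, ct$case_id)
  color <- switch(color_by,
    emergency = {
      em <- ct$emergency[m]
      grp <- rep("unknown", length(em))
      grp[!is.na(em) & em <= 2] <- "severe"
      grp[!is.na(em) & em == 3] <- "moderate"
      grp[!is.na(em) & em >= 4] <- "mild"
      grp
    },
    variant = unname(case_variants(log)[match(log$case_id,
                                              names(case_variants(log)))]),
    activity = log$activity)
  data.frame(case_id = log$case_id, case_rank = rank[m],
             timestamp = log$timestamp, color = color,
             stringsAsFactors = FALSE)
}

#' Export a DFG to Graphviz DOT
#'
#' @param dfg a [build_dfg()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dfg_dot <- function(dfg, path) {
  q <- function(x) sprintf('"%s"', gsub('"', '\\\\"', x))
  lines <- c("digraph dfg {", "  rankdir=LR;",
             sprintf("  %s;", q(dfg$nodes)),
             sprintf('  %s -> %s [label="%d | %.1f min"];',
                     q(dfg$edges$from), q(dfg$edges$to), dfg$edges$frequency,
                     dfg$edges$avg_duration / 60),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export DFG edges as tidy CSV
#'
#' @param dfg a [build_dfg()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dfg_csv <- function(dfg, path) {
  utils::write.csv(dfg$edges, path, row.names = FALSE)
  invisible(path)
}

#' Dotted chart of an event log
#'
#' Base-graphics dotted chart: one point per event, cases ranked by first
#' event, coloured by urgency group, variant or activity.
#'
#' @param x an `erlog`.
#' @param color_by passed to [dotted_chart_data()].
#' @param ... further arguments to [graphics::plot()].
#' @return the point data, invisibly.
#' @export
plot.erlog <- function(x, color_by = "emergency", ...) {
  pts <- dotted_chart_data(x, color_by)
  keys <- unique(pts$color)
  pal <- if (identical(color_by, "emergency")) {
    c(severe = "red", moderate = "orange", mild = "forestgreen",
      unknown = "grey60")[keys]
  } else {
    stats::setNames(grDevices::hcl.colors(max(3L, length(keys)), "Dark 3")[
      seq_along(keys)], keys)
  }
  graphics::plot(as.POSIXct(pts$timestamp, origin = "1970-01-01", tz = "UTC"),
                 pts$case_rank, col = pal[pts$color], pch = 16, cex = 0.4,
                 xlab = "time", ylab = "case (ranked by arrival)", ...)
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(pts)
}
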