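# Rally rhythm and groundstroke executive timing.

#' Rally rhythm from near-player impact times
#'
#' Only the near player's impacts are detected acoustically; one opponent
#' shot falls inside every same-player interval. The instantaneous frequency
#' of a same-player interval dt is therefore 120/dt shots/min (two rally
#' shots per cycle), the inferred total number of rally shots is `2n - 1`,
#' and the average frequency is `(2n - 1) / span * 60` over the first-to-last
#' span. Set `convention = "per_interval"` for the plain `60/dt`, `n/span`
#' reading.
#'
#' @param near_impact_times sorted numeric vector (seconds), length >= 2.
#' @param convention `"same_player_cycle"` (default) or `"per_interval"`.
#' @return a `rally_report`: list with `impact_times`, `instantaneous_freq`
#'   (shots/min per interval), `inferred_total_shots`, `span_s`,
#'   `average_freq` (shots/min).
#' @export
rally_rhythm <- function(near_impact_times,
                         convention = c("same_player_cycle", "per_interval")) {
  convention <- match.arg(convention)
  t <- as.numeric(near_impact_times)
  if (length(t) < 2) stopf("need at least 2 impact times")
  if (is.unsorted(t, strictly = TRUE)) stopf("impact times must be strictly increasing")
  n <- length(t)
  span <- t[n] - t[1]
  per_shot <- if (convention == "same_player_cycle") 120 else 60
  total <- if (convention == "same_player_cycle") 2L * n - 1L else n
  structure(list(
    impact_times = t,
    instantaneous_freq = per_shot / diff(t),
    inferred_total_shots = total,
    span_s = span,
    average_freq = total / span * 60,
    convention = convention), class = "rally_report")
}

#' @export
print.rally_report <- function(x, ...) {
  cat(sprintf(paste0("<rally_report> %d near-player impacts (%d total shots ",
                     "inferred) in %.2f s\n  average %.2f shots/min; ",
                     "instantaneous %s\n"),
              length(x$impact_times), x$inferred_total_shots, x$span_s,
              x$average_freq,
              paste(sprintf("%.1f", x$instantaneous_freq), collapse = ", ")))
  invisible(x)
}

#' Executive timing of groundstrokes
#'
#' For each impact paired with a rebound, the executive timing is
#' `t_impact - t_rebound` in seconds (positive by construction of the rebound
#' window). Unpaired impacts are skipped and counted as missing.
#'
#' @param events event records from [classify_events()] (columns `time_s`,
#'   `label`, `impact_id`).
#' @return data frame with `impact_time_s`, `rebound_time_s`, `timing_s`;
#'   attribute `n_unpaired` counts impacts without an accepted rebound.
#' @export
executive_timing <- function(events) {
  need <- c("time_s", "label", "impact_id")
  if (!all(need %in% names(events)))
    stopf("events must have columns: %s", paste(need, collapse = ", "))
  imps <- events[events$label == "impact", , drop = FALSE]
  rebs <- events[events$label == "rebound", , drop = FALSE]
  m <- merge(imps[, c("impact_id", "time_s")],
             rebs[, c("impact_id", "time_s")],
             by = "impact_id", suffixes = c("_impact", "_rebound"))
  out <- data.frame(impact_time_s = m$time_s_impact,
                    rebound_time_s = m$time_s_rebound,
                    timing_s = m$time_s_impact - m$time_s_rebound)
  out <- out[order(out$impact_time_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unpaired") <- nrow(imps) - nrow(out)
  out
}

#' Summarize executive timings
#'
#' Median and interquartile range (linear-interpolation quantiles, type 7)
#' plus valid/missing bookkeeping against a known number of shots.
#'
#' @param records timing records from [executive_timing()] (or a numeric
#'   vector of timings).
#' @param ground_truth_n reference number of shots (optional); missing =
#'   `ground_truth_n - n_valid`.
#' @return a `timing_summary`: list with `n_valid`, `n_missing`, `median_s`,
#'   `iqr_s`.
#' @export
summarize_timing <- function(records, ground_truth_n = NULL) {
  timings <- if (is.data.frame(records)) records$timing_s else as.numeric(records)
  n <- length(timings)
  med <- if (n) stats::median(timings) else NA_real_
  iqr <- if (n) unname(diff(stats::quantile(timings, c(0.25, 0.75), type = 7)))
         else NA_real_
  missing <- if (!is.null(ground_truth_n)) ground_truth_n - n else NA_integer_
  structure(list(n_valid = n, n_missing = missing, median_s = med,
                 iqr_s = iqr), class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  cat(sprintf("<timing_summary> n = %d (missing %s), median %.3f s; IQR %.3f s\n",
              x$n_valid,
              if (is.na(x$n_missing)) "?" else as.character(x$n_missing),
              x$median_s, x$iqr_s))
  invisible(x)
}
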