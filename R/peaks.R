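# Rule-based candidate detection. Rally impacts are picked on the raw
# normalized waveform; groundstroke candidates on the 100-400 Hz band-passed
# waveform — deliberately asymmetric, matching the two assessment protocols.

#' Peak-detection thresholds and windows
#'
#' Defaults are the validated on-court operating points: rally impacts above
#' amplitude 0.4 with >= 390 ms separation; groundstroke impact candidates
#' above 0.09 and lesser (rebound) candidates above 0.02 with >= 100 ms
#' separation; rebound search window 1.5-0.4 s before each impact.
#'
#' @param rally_amp_thresh,rally_min_sep_s rally detector threshold /
#'   minimum separation (s).
#' @param gs_impact_thresh,gs_cand_thresh,gs_min_sep_s groundstroke impact
#'   and candidate thresholds / minimum separation (s).
#' @param rebound_window_s `c(min_lag, max_lag)` seconds before an impact in
#'   which rebound candidates are accepted (closed interval).
#' @return a `peak_config` list.
#' @export
peak_config <- function(rally_amp_thresh = 0.4, rally_min_sep_s = 0.390,
                        gs_impact_thresh = 0.09, gs_cand_thresh = 0.02,
                        gs_min_sep_s = 0.100, rebound_window_s = c(0.4, 1.5)) {
  stopifnot(rebound_window_s[1] < rebound_window_s[2])
  structure(list(rally_amp_thresh = rally_amp_thresh,
                 rally_min_sep_s = rally_min_sep_s,
                 gs_impact_thresh = gs_impact_thresh,
                 gs_cand_thresh = gs_cand_thresh,
                 gs_min_sep_s = gs_min_sep_s,
                 rebound_window_s = rebound_window_s),
            class = "peak_config")
}

# local maxima of |x| above `thresh`; plateau convention: strictly greater
# than the left neighbour, at least the right neighbour
local_peaks <- function(x, thresh) {
  a <- abs(x)
  n <- length(a)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(a[i] > a[i - 1] & a[i] >= a[i + 1] & a[i] > thresh) + 1L
}

# minimum-separation thinning, greedy by descending amplitude: among peaks
# closer than min_sep only the largest survives. O(n log n): each accepted
# peak suppresses a contiguous time range of the time-sorted candidates.
enforce_min_sep <- function(times, amps, min_sep) {
  n <- length(times)
  if (n <= 1) return(seq_len(n))
  stopifnot(!is.unsorted(times))
  alive <- rep(TRUE, n)
  ord <- order(-amps, times)
  accepted <- logical(n)
  for (j in ord) {
    if (!alive[j]) next
    accepted[j] <- TRUE
    lo <- findInterval(times[j] - min_sep, times, left.open = TRUE) + 1L
    hi <- findInterval(times[j] + min_sep, times, left.open = FALSE)
    if (lo <= hi) alive[lo:hi] <- FALSE
  }
  which(accepted)
}

#' Detect rally impacts
#'
#' Local maxima of the absolute normalized waveform above the rally amplitude
#' threshold; among peaks closer than the minimum separation only the largest
#' survives.
#'
#' @param clip a normalized [audio_clip()] (raw, not band-passed).
#' @param config a [peak_config()].
#' @return data frame with columns `time_s`, `amplitude`, `kind`
#'   (`"rally_impact"`), sorted by time.
#' @export
detect_rally_impacts <- function(clip, config = peak_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  idx <- local_peaks(clip$samples, config$rally_amp_thresh)
  times <- (idx - 1) / clip$sample_rate
  amps <- abs(clip$samples[idx])
  keep <- enforce_min_sep(times, amps, config$rally_min_sep_s)
  data.frame(time_s = times[keep], amplitude = amps[keep],
             kind = rep("rally_impact", length(keep)))
}

#' Detect groundstroke impact and rebound candidates
#'
#' Operates on the band-passed waveform (see [butter_bandpass()]): lesser
#' candidates are local maxima above the candidate threshold with the
#' minimum separation enforced (greedy by amplitude); impact candidates are
#' the members of that list above the impact threshold, so
#' `impact_candidates` is a subset of `lesser_candidates`.
#'
#' @param filtered_clip the band-passed [audio_clip()] (as returned by
#'   [butter_bandpass()], which tags the clip).
#' @param config a [peak_config()].
#' @param check_filtered error if the clip does not carry the band-pass tag
#'   (default `TRUE`).
#' @return list with data frames `impact_candidates` and `lesser_candidates`
#'   (columns `time_s`, `amplitude`, `kind`).
#' @export
detect_groundstroke_candidates <- function(filtered_clip,
                                           config = peak_config(),
                                           check_filtered = TRUE) {
  stopifnot(inherits(filtered_clip, "audio_clip"))
  if (check_filtered && is.null(attr(filtered_clip, "band_passed")))
    stopf(paste("clip is not band-passed; run butter_bandpass() first",
                "(or pass check_filtered = FALSE)"))
  idx <- local_peaks(filtered_clip$samples, config$gs_cand_thresh)
  times <- (idx - 1) / filtered_clip$sample_rate
  amps <- abs(filtered_clip$samples[idx])
  keep <- enforce_min_sep(times, amps, config$gs_min_sep_s)
  lesser <- data.frame(time_s = times[keep], amplitude = amps[keep],
                       kind = rep("gs_candidate", length(keep)))
  imp <- lesser[lesser$amplitude > config$gs_impact_thresh, , drop = FALSE]
  if (nrow(imp)) imp$kind <- "gs_impact"
  rownames(imp) <- NULL
  list(impact_candidates = imp, lesser_candidates = lesser)
}

#' Assign rebound candidates to impacts by time window
#'
#' For each impact at time t, returns the lesser candidates inside the closed
#' window `[t - max_lag, t - min_lag]`, excluding candidates that are
#' themselves impact candidates.
#'
#' @param impacts,lesser_candidates data frames from
#'   [detect_groundstroke_candidates()] (time-sorted).
#' @param config a [peak_config()].
#' @return a list, one element per impact row, each a data frame of candidate
#'   rows (possibly empty).
#' @export
window_rebound_candidates <- function(impacts, lesser_candidates,
                                      config = peak_config()) {
  w <- config$rebound_window_s
  not_impact <- !(lesser_candidates$time_s %in% impacts$time_s)
  lapply(seq_len(nrow(impacts)), function(i) {
    t <- impacts$time_s[i]
    sel <- not_impact &
      lesser_candidates$time_s >= t - w[2] &
      lesser_candidates$time_s <= t - w[1]
    out <- lesser_candidates[sel, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
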