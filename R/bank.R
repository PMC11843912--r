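# Labeled training bank: the synthetic counterpart of a field-recorded
# collection of impact / rebound / noise samples.

#' Sample-bank specification
#'
#' Default class sizes are 509 (noise), 442 (rebound), 448 (impact), with
#' 0.3 s clips at 48 kHz, event-to-ambient SNR drawn uniformly from 5-25 dB,
#' and 20% of event clips carrying an overlapping non-ball transient.
#'
#' @param n_noise,n_rebound,n_impact class sizes.
#' @param clip_length_s clip length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed fixing the whole bank.
#' @param snr_range_db event SNR range (uniform) in dB.
#' @param overlap_fraction fraction of event clips with an extra overlapping
#'   noise transient.
#' @return a `bank_spec` list.
#' @export
bank_spec <- function(n_noise = 509L, n_rebound = 442L, n_impact = 448L,
                      clip_length_s = 0.3, sample_rate = 48000L, seed = 42L,
                      snr_range_db = c(5, 25), overlap_fraction = 0.2) {
  for (v in c(n_noise, n_rebound, n_impact))
    if (!is_count(v)) stopf("class counts must be non-negative integers")
  structure(list(n_noise = as.integer(n_noise),
                 n_rebound = as.integer(n_rebound),
                 n_impact = as.integer(n_impact),
                 clip_length_s = clip_length_s,
                 sample_rate = as.integer(sample_rate),
                 seed = as.integer(seed),
                 snr_range_db = snr_range_db,
                 overlap_fraction = overlap_fraction),
            class = "bank_spec")
}

#' Generate the labeled sample bank
#'
#' Impact and rebound clips contain one event whose waveform peak sits near
#' the segment anchor used at detection time (0.05 s into the clip, jittered)
#' with randomized amplitude, over ambient noise at a randomized SNR. Noise
#' clips contain ambient noise plus non-ball transients only, one of them at
#' the anchor position (mimicking a spurious detected peak).
#'
#' @param spec a [bank_spec()].
#' @return list with `clips` (list of [audio_clip()]), `labels` (factor with
#'   levels noise / rebound / impact) and `spec`.
#' @export
gen_sample_bank <- function(spec = bank_spec()) {
  stopifnot(inherits(spec, "bank_spec"))
  labels <- rep(c("noise", "rebound", "impact"),
                c(spec$n_noise, spec$n_rebound, spec$n_impact))
  fs <- spec$sample_rate
  len <- spec$clip_length_s
  n <- round(len * fs)
  kinds <- c("wind", "voice", "traffic", "crowd")

  clips <- vector("list", length(labels))
  meta <- data.frame(label = labels, amplitude = NA_real_, snr_db = NA_real_,
                     ambient = NA_character_, anchor_time_s = NA_real_,
                     transient = NA_character_, overlap = FALSE)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    sd_i <- derive_seed(spec$seed, i)
    clips[[i]] <- with_seed(sd_i, {
      anchor_t <- 0.05 + stats::runif(1, -0.02, 0.03)
      amb_kind <- sample(kinds, 1)
      amb <- gen_noise(fs, amb_kind, amplitude = 1, duration_s = len,
                       seed = derive_seed(sd_i, 1L))$samples
      amb_rms <- sqrt(mean(amb^2))
      meta$ambient[i] <- amb_kind
      meta$anchor_time_s[i] <- anchor_t
      if (lab == "noise") {
        # ambient level spans the same (log-uniform) range the event clips
        # realize through their SNR draw, so loudness itself carries no label
        x <- amb * 10^stats::runif(1, log10(7e-4), log10(0.06)) / amb_rms
        if (stats::runif(1) < 0.4) {
          # ambient-only clip: a spurious threshold-crossing bump of the
          # ambient itself, the most common false peak in deployment --
          # scaled so its band-passed peak sits just above the 0.02
          # candidate threshold, as detector-fed segments do
          bp <- apply_sos(butter_bandpass_sos(5, 100, 400, fs), amb)
          x <- amb * stats::runif(1, 0.02, 0.06) / max(abs(bp))
          meta$transient[i] <- "ambient"
        } else {
          tr <- gen_noise_transient(fs, stats::runif(1, 0.03, 0.9),
                                    derive_seed(sd_i, 2L))
          meta$transient[i] <- attr(tr, "transient_type")
          x <- add_at_peak(x, tr$samples, round(anchor_t * fs) + 1L)
          if (stats::runif(1) < 0.5) {
            tr2 <- gen_noise_transient(fs, stats::runif(1, 0.05, 0.5),
                                       derive_seed(sd_i, 3L))
            x <- add_at_peak(x, tr2$samples,
                             round(stats::runif(1, 0.05, len - 0.05) * fs) + 1L)
          }
        }
        x
      } else {
        amp <- if (lab == "impact") stats::runif(1, 0.3, 0.95)
               else stats::runif(1, 0.03, 0.25)
        ev <- if (lab == "impact") gen_impact(fs, amp, derive_seed(sd_i, 2L))
              else gen_rebound(fs, amp, derive_seed(sd_i, 2L))
        snr <- stats::runif(1, spec$snr_range_db[1], spec$snr_range_db[2])
        meta$amplitude[i] <- amp
        meta$snr_db[i] <- snr
        # SNR is the standard power ratio: event RMS over its support
        # against ambient RMS
        ev_rms <- sqrt(mean(ev$samples^2))
        x <- amb * ev_rms * 10^(-snr / 20) / amb_rms
        x <- add_at_peak(x, ev$samples, round(anchor_t * fs) + 1L)
        if (stats::runif(1) < spec$overlap_fraction) {
          meta$overlap[i] <- TRUE
          tr <- gen_noise_transient(fs, stats::runif(1, 0.2 * amp, 0.8 * amp),
                                    derive_seed(sd_i, 3L))
          x <- add_at_peak(x, tr$samples,
                           round(stats::runif(1, 0.03, len - 0.05) * fs) + 1L)
        }
        x
      }
    })
    clips[[i]] <- audio_clip(pmin(pmax(clips[[i]], -1), 1), fs)
  }
  list(clips = clips,
       labels = factor(labels, levels = c("noise", "rebound", "impact")),
       meta = meta, spec = spec)
}

# mix `add` into `base` so that add's peak lands at index `target`
add_at_peak <- function(base, add, target) {
  pk <- which.max(abs(add))
  lo <- target - pk + 1L
  ii <- seq_along(add) + lo - 1L
  keep <- ii >= 1L & ii <= length(base)
  base[ii[keep]] <- base[ii[keep]] + add[keep]
  base
}

#' Write a sample bank to disk
#'
#' One WAV per clip plus a `labels.csv` (columns `file`, `label`).
#'
#' @param bank result of [gen_sample_bank()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("clip_%04d.wav", seq_along(bank$clips))
  for (i in seq_along(bank$clips))
    write_wav(bank$clips[[i]], file.path(dir, files[i]))
  utils::write.csv(data.frame(file = files, label = as.character(bank$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a sample bank written by [write_bank()]
#' @param dir bank directory containing WAVs and `labels.csv`.
#' @return list with `clips` and `labels` as in [gen_sample_bank()].
#' @export
read_bank <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stopf("no labels.csv in %s", dir)
  tab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  clips <- lapply(file.path(dir, tab$file), read_wav)
  list(clips = clips,
       labels = factor(tab$label, levels = c("noise", "rebound", "impact")))
}
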