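#' Audio clip container
#'
#' A mono audio signal with its sample rate. Samples follow the RIFF/WAV
#' normalized-amplitude convention: values in \[-1, 1\], 0 is silence.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (positive integer).
#' @return an object of class `audio_clip`: a list with elements `samples`
#'   (numeric) and `sample_rate` (integer).
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 48000)), 48000)
#' duration(clip)
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stopf("samples must be numeric")
  if (!is_count(sample_rate) || sample_rate <= 0)
    stopf("sample_rate must be a positive integer")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %d Hz (%.3f s), peak |amp| %.4f\n",
              length(x$samples), x$sample_rate, duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an [audio_clip()].
#' @return duration in seconds.
#' @export
duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate
}

#' Normalize a clip to the \[-1, 1\] amplitude convention
#'
#' Divides by the peak absolute amplitude when it exceeds 1; already-compliant
#' clips are returned unchanged, so normalization is idempotent.
#'
#' @param clip an [audio_clip()].
#' @return a normalized `audio_clip`.
#' @export
normalize_clip <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  peak <- if (length(clip$samples)) max(abs(clip$samples)) else 0
  if (peak > 1) clip$samples <- clip$samples / peak
  clip
}
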