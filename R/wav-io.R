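# RIFF/WAVE read & write. No WAV codec is available in the installed R stack,
# so the container is parsed directly: PCM 16/24-bit and IEEE float32 are
# supported, which covers commercial action-camera audio.

#' Read a WAV file as a normalized mono clip
#'
#' Integer PCM samples are divided by the type maximum (2^15 for 16-bit,
#' 2^23 for 24-bit) so amplitudes land in \[-1, 1); float data is read as-is.
#' Stereo (or any multichannel) audio is mixed down to mono by the arithmetic
#' channel mean.
#'
#' @param path path to a PCM 16/24-bit or IEEE float32 WAV file.
#' @return an [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stopf("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stopf("not a WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2,
                               signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size)
        stopf("truncated WAV data chunk in %s", path)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))  # skip, chunks are padded
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stopf("missing fmt/data chunk in %s", path)
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; sub-format is ignored, bits decide
  if (!fmt$audio_format %in% c(1L, 3L, 65534L))
    stopf("unsupported WAV encoding (format tag %d) in %s",
          fmt$audio_format, path)

  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = {
      if (fmt$audio_format == 1L)
        readBin(data_raw, "integer", length(data_raw) / 4, 4,
                endian = "little") / 2147483648
      else
        readBin(data_raw, "double", length(data_raw) / 4, 4,
                endian = "little")
    },
    stopf("unsupported WAV bit depth %d in %s", fmt$bits, path)
  )
  nc <- fmt$n_channels
  if (nc > 1L) {
    n_frames <- length(x) %/% nc
    x <- colMeans(matrix(x[seq_len(n_frames * nc)], nrow = nc))
  }
  audio_clip(x, fmt$sample_rate)
}

#' Write a clip to a WAV file
#'
#' Samples outside \[-1, 1\] are saturated to the limits with a warning before
#' quantization.
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @param bit_depth one of `"16"`, `"24"`, `"float32"` (default 16-bit PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = c("16", "24", "float32")) {
  stopifnot(inherits(clip, "audio_clip"))
  bit_depth <- match.arg(as.character(bit_depth[1]),
                         c("16", "24", "float32"))
  x <- clip$samples
  if (length(x) && max(abs(x)) > 1) {
    warnf("write_wav: %d sample(s) outside [-1, 1] saturated",
          sum(abs(x) > 1))
    x <- pmin(pmax(x, -1), 1)
  }
  fs <- clip$sample_rate
  bits <- switch(bit_depth, "16" = 16L, "24" = 24L, "float32" = 32L)
  fmt_tag <- if (bit_depth == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")

  if (bit_depth == "16") {
    q <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
    writeBin(q, con, 2, endian = "little")
  } else if (bit_depth == "24") {
    q <- pmin(pmax(round(x * 8388608), -8388608), 8388607)
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
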