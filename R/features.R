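# Per-segment feature extraction. The base set (spectrogram per-bin
# statistics, argmax-energy frequency, ZCR, spectral centroid, MFCCs,
# time-domain statistics) feeds the impact-versus-noise model; the extended
# set adds tonnetz, spectral contrast and chroma for the harder
# rebound-versus-noise problem. No MFCC/chroma implementation exists in the
# installed R stack, so the standard definitions are implemented here.

#' Extract a fixed-length segment around a peak
#'
#' Returns a `pre_s + post_s` second segment centred `pre_s` before the peak,
#' zero-padded where the window leaves the clip.
#'
#' @param clip an [audio_clip()].
#' @param peak_time peak time in seconds.
#' @param pre_s,post_s seconds before/after the peak (defaults 0.05 / 0.25).
#' @return an [audio_clip()] of exactly `round((pre_s + post_s) *
#'   sample_rate)` samples.
#' @export
extract_segment <- function(clip, peak_time, pre_s = 0.05, post_s = 0.25) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  pk <- round(peak_time * fs) + 1L
  idx <- (pk - n_pre):(pk + n_post - 1L)
  out <- numeric(length(idx))
  keep <- idx >= 1L & idx <= length(clip$samples)
  out[keep] <- clip$samples[idx[keep]]
  audio_clip(out, fs)
}

#' Base feature vector of an audio segment
#'
#' Per-frequency-bin spectrogram mean / standard deviation / maximum, the
#' frequency of maximum energy, zero-crossing rate, spectral centroid, MFCC
#' means, overall time-domain mean / sd, and windowed time-domain
#' min / max / mean / sd over `n_windows` equal sub-segments.
#'
#' @param segment an [audio_clip()] at least one STFT window long.
#' @param window_len,hop,pad_to STFT parameters, see [stft_spectrogram()].
#' @param n_mfcc number of MFCC coefficients (default 13).
#' @param n_windows number of time-domain sub-windows (default 10).
#' @return named numeric vector of fixed length for a given configuration;
#'   non-finite values are imputed to 0 with a warning.
#' @export
base_features <- function(segment, window_len = 320L, hop = 160L,
                          pad_to = 512L, n_mfcc = 13L, n_windows = 10L) {
  sg <- stft_spectrogram(segment, window_len, hop, pad_to)
  m <- sg$magnitudes
  nb <- nrow(m)
  bin_mean <- rowMeans(m)
  bin_sd <- apply(m, 1, stats::sd)
  bin_max <- apply(m, 1, max)
  energy_per_bin <- rowSums(m^2)
  argmax_freq <- if (sum(energy_per_bin) > 0)
    sg$bin_freqs_hz[which.max(energy_per_bin)] else 0
  x <- segment$samples
  pos <- x >= 0
  zcr <- if (length(x) > 1) mean(pos[-1] != pos[-length(x)]) else 0
  centroid <- if (sum(bin_mean) > 0)
    sum(sg$bin_freqs_hz * bin_mean) / sum(bin_mean) else 0
  mf <- mfcc_means(m, sg$bin_freqs_hz, segment$sample_rate, n_mfcc)
  wl <- floor(length(x) / n_windows)
  wm <- matrix(x[seq_len(wl * n_windows)], nrow = wl)
  feats <- c(
    stats::setNames(bin_mean, sprintf("spec_mean_%03d", seq_len(nb))),
    stats::setNames(bin_sd, sprintf("spec_sd_%03d", seq_len(nb))),
    stats::setNames(bin_max, sprintf("spec_max_%03d", seq_len(nb))),
    argmax_freq_hz = argmax_freq,
    zcr = zcr,
    spectral_centroid_hz = centroid,
    stats::setNames(mf, sprintf("mfcc_%02d", seq_len(n_mfcc))),
    td_mean = mean(x), td_sd = stats::sd(x),
    stats::setNames(apply(wm, 2, min), sprintf("win_min_%02d", seq_len(n_windows))),
    stats::setNames(apply(wm, 2, max), sprintf("win_max_%02d", seq_len(n_windows))),
    stats::setNames(colMeans(wm), sprintf("win_mean_%02d", seq_len(n_windows))),
    stats::setNames(apply(wm, 2, stats::sd), sprintf("win_sd_%02d", seq_len(n_windows)))
  )
  impute_nonfinite(feats)
}

#' Extended feature vector (base + tonnetz, spectral contrast, chroma)
#'
#' @inheritParams base_features
#' @param n_contrast_bands number of octave contrast bands above the first
#'   cutoff (default 6, giving `n_contrast_bands + 1` values).
#' @return named numeric vector: [base_features()] plus `tonnetz_1..6`,
#'   `contrast_1..7`, `chroma_01..12`.
#' @export
extended_features <- function(segment, window_len = 320L, hop = 160L,
                              pad_to = 512L, n_mfcc = 13L, n_windows = 10L,
                              n_contrast_bands = 6L) {
  base <- base_features(segment, window_len, hop, pad_to, n_mfcc, n_windows)
  sg <- stft_spectrogram(segment, window_len, hop, pad_to)
  ch <- chroma_frames(sg)
  tz <- tonnetz_from_chroma(ch)
  sc <- spectral_contrast(sg, n_bands = n_contrast_bands)
  impute_nonfinite(c(
    base,
    stats::setNames(rowMeans(tz), sprintf("tonnetz_%d", 1:6)),
    stats::setNames(rowMeans(sc), sprintf("contrast_%d", seq_len(nrow(sc)))),
    stats::setNames(rowMeans(ch), sprintf("chroma_%02d", 1:12))
  ))
}

impute_nonfinite <- function(feats) {
  bad <- !is.finite(feats)
  if (any(bad)) {
    warnf("%d non-finite feature value(s) imputed to 0", sum(bad))
    feats[bad] <- 0
  }
  feats
}

# mel filterbank MFCCs: triangular filters on the one-sided power spectrum,
# log energies, orthonormal DCT-II, coefficients averaged over frames
mfcc_means <- function(magnitudes, bin_freqs, fs, n_mfcc, n_mels = 26L) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel2hz(seq(hz2mel(0), hz2mel(fs / 2), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (j in seq_len(n_mels)) {
    lo <- edges[j]; cen <- edges[j + 1]; hi <- edges[j + 2]
    up <- (bin_freqs - lo) / (cen - lo)
    down <- (hi - bin_freqs) / (hi - cen)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  mel_energy <- fb %*% (magnitudes^2)
  log_mel <- log(mel_energy + 1e-10)
  k <- seq_len(n_mfcc) - 1L
  dct <- sqrt(2 / n_mels) *
    cos(outer(k, (seq_len(n_mels) - 0.5), function(a, b) pi * a * b / n_mels))
  dct[1, ] <- dct[1, ] / sqrt(2)
  rowMeans(dct %*% log_mel)
}

# fold spectral magnitude into 12 pitch classes (A440 reference, C first),
# each frame normalized to sum 1 where nonzero
chroma_frames <- function(sg) {
  f <- sg$bin_freqs_hz
  keep <- f > 0
  pc <- (round(12 * log2(f[keep] / 440)) + 9L) %% 12L  # 0 = C
  ch <- rowsum(sg$magnitudes[keep, , drop = FALSE], group = pc)
  full <- matrix(0, 12, ncol(ch),
                 dimnames = list(as.character(0:11), NULL))
  full[rownames(ch), ] <- ch
  tot <- colSums(full)
  tot[tot == 0] <- 1
  sweep(full, 2, tot, "/")
}

# 6-D harmonic-network (tonnetz) projection of L1-normalized chroma
tonnetz_from_chroma <- function(chroma) {
  j <- 0:11
  phi <- rbind(
    sin(j * 7 * pi / 6), cos(j * 7 * pi / 6),
    sin(j * 3 * pi / 2), cos(j * 3 * pi / 2),
    0.5 * sin(j * 2 * pi / 3), 0.5 * cos(j * 2 * pi / 3))
  phi %*% chroma
}

# octave-band spectral contrast: log(mean top alpha-fraction) minus
# log(mean bottom alpha-fraction) per band per frame
spectral_contrast <- function(sg, n_bands = 6L, fmin = 200, alpha = 0.02) {
  f <- sg$bin_freqs_hz
  edges <- c(0, fmin * 2^(0:n_bands))
  edges[length(edges)] <- max(edges[length(edges)], max(f) + 1)
  out <- matrix(0, n_bands + 1L, ncol(sg$magnitudes))
  for (b in seq_len(n_bands + 1L)) {
    sel <- f >= edges[b] & f < edges[b + 1]
    if (!any(sel)) next
    sub <- sg$magnitudes[sel, , drop = FALSE]
    k <- max(1L, ceiling(alpha * nrow(sub)))
    out[b, ] <- apply(sub, 2, function(col) {
      s <- sort(col)
      log(mean(s[seq(length(s) - k + 1L, length(s))]) + 1e-10) -
        log(mean(s[seq_len(k)]) + 1e-10)
    })
  }
  out
}

#' Feature matrix for a list of segments
#'
#' @param clips list of [audio_clip()] segments.
#' @param type `"base"` or `"extended"`.
#' @param ... passed to [base_features()] / [extended_features()].
#' @return numeric matrix, one row per clip, feature names as columns.
#' @export
feature_matrix <- function(clips, type = c("base", "extended"), ...) {
  type <- match.arg(type)
  fn <- if (type == "base") base_features else extended_features
  rows <- lapply(clips, fn, ...)
  do.call(rbind, rows)
}

#' ANOVA F-test feature selection (best k)
#'
#' Per-feature one-way ANOVA F statistic (between-class mean square over
#' within-class mean square); the top `k` features by F are selected, ties
#' broken by lower column index. A feature constant everywhere gets F = 0.
#'
#' @param features numeric matrix (samples x features).
#' @param labels class labels (>= 2 classes, >= 2 samples per class).
#' @param k number of features to keep (capped at `ncol(features)` with a
#'   warning); `NULL` keeps every feature (identity selection).
#' @return a `selection_result`: list with `indices`, `f_statistic`, `k`.
#' @export
anova_f_select <- function(features, labels, k) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stopf("need at least 2 classes")
  labels <- droplevels(labels)
  n <- nrow(features)
  g <- nlevels(labels)
  if (min(table(labels)) < 2) stopf("need >= 2 samples per class")
  if (is.null(k)) k <- ncol(features)
  if (k > ncol(features)) {
    warnf("k = %d exceeds %d features; capped", k, ncol(features))
    k <- ncol(features)
  }
  counts <- as.vector(table(labels))
  grand <- colMeans(features)
  group_means <- rowsum(features, labels) / counts
  ssb <- colSums(counts * sweep(group_means, 2, grand)^2)
  sst <- colSums(sweep(features, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw == 0 & ssb <= sqrt(.Machine$double.eps)] <- 0
  f[ssw == 0 & is.infinite(f)] <- Inf
  ord <- order(-f, seq_along(f))
  structure(list(indices = sort(ord[seq_len(k)]), f_statistic = f, k = k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> k = %d of %d features (max F = %.3g)\n",
              x$k, length(x$f_statistic), max(x$f_statistic)))
  invisible(x)
}
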