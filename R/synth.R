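# Synthetic court-audio generation. The three sound classes follow their
# qualitative acoustic signatures: impacts are sharp broadband bursts with
# most energy above 500 Hz plus a small low-frequency "body" component (real
# string impacts carry audible frame/board energy inside 100-400 Hz, which is
# what makes them visible to the band-passed groundstroke detector); rebounds
# are longer, quieter damped oscillations concentrated in 100-400 Hz; noise
# is ambient (wind, voices, traffic, crowd) plus non-ball transients. All
# synthesis recipes are parametric and deterministic in their seed.

#' Generate a ball-racket impact sound
#'
#' A ~30 ms burst: exponentially damped sinusoidal partials in
#' `freq_range` plus high-passed noise, with a weaker damped low-frequency
#' body component (150-350 Hz). Peak absolute amplitude equals `amplitude`.
#'
#' @param sample_rate sampling rate in Hz.
#' @param amplitude peak normalized amplitude in (0, 1].
#' @param seed integer seed; the clip is a pure function of seed + parameters.
#' @param duration_s clip length in seconds (default 0.03).
#' @param freq_range range of the main partials in Hz (default 600-4000).
#' @param body_fraction relative amplitude of the low-frequency body
#'   component (default 0.35).
#' @return an [audio_clip()].
#' @export
gen_impact <- function(sample_rate = 48000L, amplitude = 0.8, seed = 1L,
                       duration_s = 0.03, freq_range = c(600, 4000),
                       body_fraction = 0.35) {
  check_amplitude(amplitude)
  with_seed(seed, {
    n <- round(duration_s * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    # percussive core: broadband burst across the impact band, fast decay
    bw <- c(stats::runif(1, 0.8 * freq_range[1], 1.5 * freq_range[1]),
            stats::runif(1, 0.9 * freq_range[2], 1.5 * freq_range[2]))
    bb <- shape_noise(n, sample_rate,
                      function(f) as.numeric(f >= bw[1] & f <= bw[2]) /
                        sqrt(1 + (f / 2500)^2))
    x <- bb / max(abs(bb)) * exp(-t / stats::runif(1, 0.004, 0.008))
    # string-bed ring: a few damped partials colouring the burst
    freqs <- sort(stats::runif(3, freq_range[1], freq_range[2]))
    amps <- stats::runif(3, 0.2, 0.45) / seq_len(3)
    taus <- stats::runif(3, 0.003, 0.007)
    phases <- stats::runif(3, 0, 2 * pi)
    x <- x + rowSums(vapply(seq_len(3), function(i)
      amps[i] * sin(2 * pi * freqs[i] * t + phases[i]) * exp(-t / taus[i]),
      numeric(n)))
    # low-frequency body thump inside the rebound band
    f_body <- stats::runif(1, 150, 350)
    x <- x + body_fraction * max(abs(x)) *
      sin(2 * pi * f_body * t + stats::runif(1, 0, 2 * pi)) * exp(-t / 0.012)
    ramp_n <- max(2L, round(0.0005 * sample_rate))
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * seq(0, 1, length.out = ramp_n)
    audio_clip(x / max(abs(x)) * amplitude, sample_rate)
  })
}

#' Generate a ball-ground rebound sound
#'
#' A 50-150 ms damped oscillation with dominant spectral energy inside
#' 100-400 Hz: a main partial around 140-220 Hz, a weaker one at 250-380 Hz,
#' and a little band-limited noise. Peak absolute amplitude equals
#' `amplitude`.
#'
#' @inheritParams gen_impact
#' @param duration_s clip length in seconds (default 0.08).
#' @return an [audio_clip()].
#' @export
gen_rebound <- function(sample_rate = 48000L, amplitude = 0.3, seed = 1L,
                        duration_s = 0.08) {
  check_amplitude(amplitude)
  with_seed(seed, {
    n <- round(duration_s * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    f1 <- stats::runif(1, 140, 220)
    f2 <- stats::runif(1, 250, 380)
    tau1 <- stats::runif(1, 0.012, 0.022)   # strongly damped: a short dull thud
    # percussive thump: band-limited noise burst with a damped tonal colour
    nz <- stats::rnorm(n)
    nz_bp <- apply_sos(butter_bandpass_sos(2, 100, 400, sample_rate), nz)
    x <- 0.6 * nz_bp / max(abs(nz_bp)) * exp(-t / tau1) +
      sin(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi)) * exp(-t / tau1) +
      0.4 * sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi)) *
        exp(-t / (0.6 * tau1))
    ramp_n <- max(2L, round(0.002 * sample_rate))
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * seq(0, 1, length.out = ramp_n)
    audio_clip(x / max(abs(x)) * amplitude, sample_rate)
  })
}

#' Generate ambient court noise
#'
#' Spectrally shaped noise models: `wind` (low-passed 1/f noise with slow
#' amplitude modulation), `voice` (modulated harmonic stack below 1 kHz with
#' a randomized pitch contour and syllabic gating), `traffic` (low-mid
#' broadband rumble), `crowd` (flatter broadband babble). Peak amplitude
#' equals `amplitude`.
#'
#' @inheritParams gen_impact
#' @param kind one of `"wind"`, `"voice"`, `"traffic"`, `"crowd"`.
#' @param duration_s clip length in seconds.
#' @return an [audio_clip()].
#' @export
gen_noise <- function(sample_rate = 48000L, kind = "wind", amplitude = 0.1,
                      duration_s = 1, seed = 1L) {
  check_amplitude(amplitude)
  kinds <- c("wind", "voice", "traffic", "crowd")
  if (!kind %in% kinds)
    stopf("unknown noise kind '%s' (use one of: %s)", kind,
          paste(kinds, collapse = ", "))
  with_seed(seed, {
    n <- round(duration_s * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    x <- switch(kind,
      wind = {
        y <- shape_noise(n, sample_rate,
                         function(f) 1 / sqrt(f + 20) / (1 + (f / 300)^2))
        fm <- stats::runif(1, 0.2, 0.8)
        y * (0.6 + 0.4 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi)))
      },
      voice = {
        f0 <- stats::runif(1, 110, 240)
        contour <- f0 * (1 + 0.15 * sin(2 * pi * stats::runif(1, 1, 3) * t +
                                          stats::runif(1, 0, 2 * pi)))
        h_max <- max(1, floor(1000 / f0))
        y <- 0
        for (h in seq_len(h_max)) {
          ph <- 2 * pi * cumsum(h * contour) / sample_rate
          y <- y + sin(ph + stats::runif(1, 0, 2 * pi)) / h
        }
        gate <- pmax(0.1, sin(2 * pi * stats::runif(1, 2.5, 4.5) * t +
                                stats::runif(1, 0, 2 * pi)))^2
        y * gate + 0.05 * stats::rnorm(n)
      },
      traffic = shape_noise(n, sample_rate, function(f) 1 / (1 + (f / 600)^1.5)),
      crowd = {
        y <- shape_noise(n, sample_rate, function(f) 1 / (1 + f / 2000))
        y * (0.8 + 0.2 * sin(2 * pi * stats::runif(1, 0.3, 1) * t))
      })
    audio_clip(x / max(abs(x)) * amplitude, sample_rate)
  })
}

# FFT-domain spectral shaping of white noise; gain(f) evaluated at |f|
shape_noise <- function(n, fs, gain) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  Re(stats::fft(spec * gain(f), inverse = TRUE)) / n
}

# short non-ball transient (spurious-peak material for the noise class)
gen_noise_transient <- function(sample_rate = 48000L, amplitude = 0.3,
                                seed = 1L) {
  check_amplitude(amplitude)
  with_seed(seed, {
    type <- sample(c("click", "voice_burst", "squeak"), 1)
    x <- switch(type,
      click = {
        n <- round(0.008 * sample_rate)
        stats::rnorm(n) * exp(-(seq_len(n) - 1) / (0.002 * sample_rate))
      },
      voice_burst = {
        # short shout/call: harmonic stack with formant-like weighting
        # (peaks near 500 and 1500 Hz) plus aspiration noise
        n <- round(0.15 * sample_rate)
        t <- (seq_len(n) - 1) / sample_rate
        f0 <- stats::runif(1, 120, 300)
        h_max <- floor(2500 / f0)
        y <- 0
        for (h in seq_len(h_max)) {
          fh <- h * f0
          formant <- exp(-((fh - 500) / 400)^2) + 0.7 * exp(-((fh - 1500) / 500)^2)
          y <- y + (0.3 + formant) / h * sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
        }
        (y / max(abs(y)) + 0.2 * stats::rnorm(n)) * sin(pi * t / max(t))^2
      },
      squeak = {
        # shoe squeal: sustained narrow-band tone with vibrato, slow envelope
        n <- round(0.15 * sample_rate)
        t <- (seq_len(n) - 1) / sample_rate
        f <- stats::runif(1, 1500, 4000)
        vib <- 1 + 0.02 * sin(2 * pi * stats::runif(1, 8, 16) * t)
        (sin(2 * pi * f * t * vib) +
           0.3 * sin(2 * pi * 2 * f * t * vib)) * sin(pi * t / max(t))^0.7
      })
    out <- audio_clip(x / max(abs(x)) * amplitude, sample_rate)
    attr(out, "transient_type") <- type
    out
  })
}

check_amplitude <- function(amplitude) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 ||
      !is.finite(amplitude) || amplitude <= 0 || amplitude > 1)
    stopf("amplitude must be in (0, 1], got %s", format(amplitude))
}

#' Scene specification for the scene renderer
#'
#' @param duration_s scene length in seconds.
#' @param events data frame with columns `time_s`, `kind` (impact / rebound /
#'   noise), `amplitude` (0-1], `player` (near / far / none).
#' @param ambient_kind ambient noise model, see [gen_noise()].
#' @param ambient_snr_db scene signal-to-noise ratio in dB: ambient RMS is
#'   set to (max near-event amplitude) / 10^(SNR/20).
#' @param far_attenuation amplitude factor applied to far-player events
#'   (default 0.25).
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed fixing all randomness.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(duration_s, events, ambient_kind = "wind",
                       ambient_snr_db = 30, far_attenuation = 0.25,
                       sample_rate = 48000L, seed = 1L) {
  events <- as.data.frame(events)
  need <- c("time_s", "kind", "amplitude")
  if (!all(need %in% names(events)))
    stopf("events must have columns: %s", paste(need, collapse = ", "))
  if (is.null(events$player)) events$player <- rep("near", nrow(events))
  if (nrow(events) && any(events$time_s < 0 | events$time_s >= duration_s))
    stopf("all event times must lie in [0, duration_s)")
  structure(list(duration_s = duration_s, events = events,
                 ambient_kind = ambient_kind, ambient_snr_db = ambient_snr_db,
                 far_attenuation = far_attenuation,
                 sample_rate = as.integer(sample_rate), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a scene into audio plus ground truth
#'
#' Events are mixed additively over ambient noise; each event clip is placed
#' so its waveform peak lands exactly on the annotated time. Far-player
#' events are attenuated by `far_attenuation`.
#'
#' @param spec a [scene_spec()].
#' @return list with `clip` (an [audio_clip()]) and `truth` (data frame
#'   `time_s`, `label`, `amplitude`, `player`): the injected event times and
#'   realized peak amplitudes.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration_s * fs)
  ev <- spec$events
  near_amp <- if (any(ev$player == "near")) max(ev$amplitude[ev$player == "near"]) else 1
  amb <- gen_noise(fs, spec$ambient_kind, amplitude = 1, duration_s = spec$duration_s,
                   seed = derive_seed(spec$seed, 0L))
  rms <- sqrt(mean(amb$samples^2))
  x <- amb$samples * (near_amp * 10^(-spec$ambient_snr_db / 20)) / rms

  truth <- ev[0, c("time_s", "kind", "amplitude", "player")]
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      amp <- ev$amplitude[i] *
        if (identical(ev$player[i], "far")) spec$far_attenuation else 1
      sd_i <- derive_seed(spec$seed, i)
      g <- switch(as.character(ev$kind[i]),
        impact = gen_impact(fs, amp, sd_i),
        rebound = gen_rebound(fs, amp, sd_i),
        noise = gen_noise_transient(fs, amp, sd_i),
        stopf("unknown event kind '%s'", ev$kind[i]))
      target <- round(ev$time_s[i] * fs) + 1L
      pk <- which.max(abs(g$samples))
      lo <- target - pk + 1L
      ii <- seq_along(g$samples) + lo - 1L
      keep <- ii >= 1L & ii <= n
      x[ii[keep]] <- x[ii[keep]] + g$samples[keep]
      truth <- rbind(truth, data.frame(
        time_s = (target - 1L) / fs, kind = as.character(ev$kind[i]),
        amplitude = amp, player = as.character(ev$player[i])))
    }
    names(truth)[2] <- "label"
  } else names(truth)[2] <- "label"
  if (any(abs(x) > 1)) {
    warnf("render_scene: %d sample(s) clipped to [-1, 1]", sum(abs(x) > 1))
    x <- pmin(pmax(x, -1), 1)
  }
  truth <- truth[order(truth$time_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(clip = audio_clip(x, fs), truth = truth)
}

#' Preset scenes for the reference assessment scenarios
#'
#' * `rally1`: 8 near-player impacts (15 total hits with the attenuated
#'   opponent's) whose first-to-last span is 23.03 s.
#' * `rally2`: 7 near-player impacts (13 total hits), span 18.29 s.
#' * `g1`: forehand drill, rebound-impact executive timing around a 0.81 s
#'   median (amateur group).
#' * `g2`: as `g1` with timing around a 0.56 s median (experienced group).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param n_shots number of shots for the `g1`/`g2` drills (default 20).
#' @param ambient_snr_db scene SNR in dB (defaults: 30 for rallies, 25 for
#'   drills).
#' @return a [scene_spec()].
#' @export
scene_preset <- function(name = c("rally1", "rally2", "g1", "g2"), seed = 1L,
                         n_shots = 20L, ambient_snr_db = NULL) {
  name <- match.arg(name)
  if (name %in% c("rally1", "rally2")) {
    n_near <- if (name == "rally1") 8L else 7L
    span <- if (name == "rally1") 23.03 else 18.29
    t0 <- 0.5
    near_t <- t0 + (seq_len(n_near) - 1) * span / (n_near - 1)
    far_t <- (near_t[-1] + near_t[-n_near]) / 2
    ev <- with_seed(seed, rbind(
      data.frame(time_s = near_t, kind = "impact",
                 amplitude = stats::runif(n_near, 0.55, 0.95), player = "near"),
      data.frame(time_s = far_t, kind = "impact",
                 amplitude = stats::runif(n_near - 1L, 0.55, 0.95),
                 player = "far")))
    scene_spec(span + 2 * t0, ev, ambient_kind = "wind",
               ambient_snr_db = if (is.null(ambient_snr_db)) 30 else ambient_snr_db,
               seed = seed)
  } else {
    med <- if (name == "g1") 0.81 else 0.56
    with_seed(seed, {
      timing <- pmin(pmax(stats::rnorm(n_shots, med, 0.05), 0.45), 1.4)
      imp_t <- 2 + (seq_len(n_shots) - 1) * 3.5
      ev <- rbind(
        data.frame(time_s = imp_t, kind = "impact",
                   amplitude = stats::runif(n_shots, 0.4, 0.9), player = "near"),
        data.frame(time_s = imp_t - timing, kind = "rebound",
                   amplitude = stats::runif(n_shots, 0.025, 0.08),
                   player = "near"))
      scene_spec(max(imp_t) + 2, ev,
                 ambient_kind = if (name == "g1") "wind" else "crowd",
                 ambient_snr_db = if (is.null(ambient_snr_db)) 25 else ambient_snr_db,
                 seed = seed)
    })
  }
}
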