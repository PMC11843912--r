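# shared fixtures, built in code and cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small labeled bank: big enough to train mechanically meaningful models,
# small enough to keep module tests fast
tiny_bank <- function() {
  cached("tiny_bank", function()
    gen_sample_bank(bank_spec(n_noise = 30L, n_rebound = 25L, n_impact = 25L,
                              seed = 402L)))
}

tiny_bundle <- function() {
  cached("tiny_bundle", function()
    train_court_models(tiny_bank(), seed = 7L))
}

# brute-force reference for the minimum-separation peak rule: enumerate local
# maxima, accept greedily by descending amplitude with O(n^2) scanning
bf_min_sep <- function(times, amps, min_sep) {
  ord <- order(-amps, times)
  acc_t <- numeric(0)
  acc_i <- integer(0)
  for (j in ord) {
    if (all(abs(times[j] - acc_t) >= min_sep) || !length(acc_t)) {
      acc_t <- c(acc_t, times[j])
      acc_i <- c(acc_i, j)
    }
  }
  sort(acc_i)
}

bf_local_maxima <- function(x, thresh) {
  a <- abs(x)
  out <- integer(0)
  for (i in seq(2, length(a) - 1)) {
    if (a[i] > a[i - 1] && a[i] >= a[i + 1] && a[i] > thresh) out <- c(out, i)
  }
  out
}

# random sparse test signal with controlled impulse times/amplitudes
impulse_signal <- function(times_s, amps, fs = 1000L, duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- max(times_s) + 0.5
  x <- numeric(round(duration_s * fs))
  x[round(times_s * fs) + 1L] <- amps
  audio_clip(x, fs)
}
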