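test_that("rally detection applies the amplitude/interval rule", {
  cfg <- peak_config()
  close_pair <- impulse_signal(c(1.0, 1.3), c(0.8, 0.6))
  pk <- detect_rally_impacts(close_pair, cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$amplitude, 0.8)

  far_pair <- impulse_signal(c(1.0, 1.5), c(0.8, 0.6))
  expect_equal(nrow(detect_rally_impacts(far_pair, cfg)), 2)

  quiet <- impulse_signal(c(1.0, 2.0), c(0.3, 0.39))
  expect_equal(nrow(detect_rally_impacts(quiet, cfg)), 0)
})

test_that("groundstroke candidates obey both thresholds and nesting", {
  cfg <- peak_config()
  clip <- impulse_signal(1.0, 0.10)
  attr(clip, "band_passed") <- c(100, 400)
  out <- detect_groundstroke_candidates(clip, cfg)
  expect_equal(nrow(out$impact_candidates), 1)
  expect_equal(nrow(out$lesser_candidates), 1)

  close2 <- impulse_signal(c(1.00, 1.05), c(0.05, 0.03))
  attr(close2, "band_passed") <- c(100, 400)
  out2 <- detect_groundstroke_candidates(close2, cfg)
  expect_equal(out2$lesser_candidates$amplitude, 0.05)
  expect_equal(nrow(out2$impact_candidates), 0)

  silent <- audio_clip(numeric(2000), 1000L)
  attr(silent, "band_passed") <- c(100, 400)
  out3 <- detect_groundstroke_candidates(silent, cfg)
  expect_equal(nrow(out3$impact_candidates), 0)
  expect_equal(nrow(out3$lesser_candidates), 0)

  expect_error(detect_groundstroke_candidates(impulse_signal(1, 0.5), cfg),
               "band-passed")
})

test_that("impact candidates are a subset of lesser candidates", {
  set.seed(21)
  for (i in 1:10) {
    x <- numeric(4000)
    idx <- sample(10:3990, 40)
    x[idx] <- runif(40, 0, 0.5)
    clip <- audio_clip(x, 1000L)
    attr(clip, "band_passed") <- c(100, 400)
    out <- detect_groundstroke_candidates(clip)
    expect_true(all(out$impact_candidates$time_s %in%
                      out$lesser_candidates$time_s))
    expect_false(is.unsorted(out$lesser_candidates$time_s, strictly = TRUE))
    expect_true(all(diff(out$lesser_candidates$time_s) >= 0.100 - 1e-12))
  }
})

test_that("detectors match the brute-force rule on random signals", {
  set.seed(7)
  for (i in 1:20) {
    x <- numeric(3000)
    idx <- sample(5:2995, 60)
    x[idx] <- runif(60) * sample(c(-1, 1), 60, replace = TRUE)
    clip <- audio_clip(x, 1000L)
    pk <- detect_rally_impacts(clip)
    cand_idx <- bf_local_maxima(x, 0.4)
    keep <- bf_min_sep((cand_idx - 1) / 1000, abs(x[cand_idx]), 0.390)
    expect_equal(pk$time_s, (cand_idx[keep] - 1) / 1000)
    expect_equal(pk$amplitude, abs(x[cand_idx[keep]]))
  }
})

test_that("raising a threshold never adds rally peaks", {
  set.seed(9)
  x <- numeric(5000)
  idx <- sample(5:4995, 100)
  x[idx] <- runif(100)
  clip <- audio_clip(x, 1000L)
  lo <- detect_rally_impacts(clip, peak_config(rally_amp_thresh = 0.3))
  hi <- detect_rally_impacts(clip, peak_config(rally_amp_thresh = 0.5))
  expect_true(all(hi$time_s %in% lo$time_s))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("rebound windowing keeps the closed 1.5-0.4 s pre-impact interval", {
  cfg <- peak_config()
  impacts <- data.frame(time_s = 10.0, amplitude = 0.2, kind = "gs_impact")
  lesser <- data.frame(time_s = c(8.4, 8.9, 9.19, 9.2, 9.6, 9.8, 10.0),
                       amplitude = c(0.03, 0.04, 0.05, 0.03, 0.06, 0.04, 0.2),
                       kind = "gs_candidate")
  w <- window_rebound_candidates(impacts, lesser, cfg)
  expect_length(w, 1)
  expect_equal(w[[1]]$time_s, c(8.9, 9.19, 9.2, 9.6))  # 8.4 < t-1.5 is out...
  # boundary cases: exactly t - 1.5 and t - 0.4 are included (closed interval)
  lesser2 <- data.frame(time_s = c(8.5, 9.6), amplitude = c(0.03, 0.03),
                        kind = "gs_candidate")
  w2 <- window_rebound_candidates(impacts, lesser2, cfg)
  expect_equal(w2[[1]]$time_s, c(8.5, 9.6))
  # candidates that are themselves impacts are excluded
  impacts3 <- data.frame(time_s = c(9.2, 10.0), amplitude = c(0.1, 0.2),
                         kind = "gs_impact")
  w3 <- window_rebound_candidates(impacts3, lesser, cfg)
  expect_false(9.2 %in% w3[[2]]$time_s)
  expect_true(9.19 %in% w3[[2]]$time_s)
})
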