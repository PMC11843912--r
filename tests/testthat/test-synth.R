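test_that("generated sounds scale their peak exactly and are seed-pure", {
  for (gen in list(function(a, s) gen_impact(amplitude = a, seed = s),
                   function(a, s) gen_rebound(amplitude = a, seed = s),
                   function(a, s) gen_noise(amplitude = a, seed = s))) {
    expect_equal(max(abs(gen(0.8, 3)$samples)), 0.8)
    expect_equal(max(abs(gen(0.05, 3)$samples)), 0.05)
    expect_identical(gen(0.5, 11)$samples, gen(0.5, 11)$samples)
    expect_false(identical(gen(0.5, 11)$samples, gen(0.5, 12)$samples))
  }
  expect_error(gen_impact(amplitude = 0), "amplitude")
  expect_error(gen_rebound(amplitude = 1.2), "amplitude")
  expect_error(gen_noise(kind = "helicopter"), "unknown noise kind")
})

test_that("impact is brighter than rebound at equal amplitude", {
  imp <- gen_impact(amplitude = 0.5, seed = 5)
  reb <- gen_rebound(amplitude = 0.5, seed = 5)
  cent <- function(clip) {
    n <- 0.3 * clip$sample_rate
    padded <- audio_clip(c(clip$samples, numeric(n - length(clip$samples))),
                         clip$sample_rate)
    unname(base_features(padded)["spectral_centroid_hz"])
  }
  expect_gt(cent(imp), cent(reb))
})

test_that("rebound energy sits in the 100-400 Hz band", {
  for (s in 1:5) {
    reb <- gen_rebound(amplitude = 0.3, seed = s)
    sg <- stft_spectrogram(reb, window_len = 1024L, hop = 512L, pad_to = 4096L)
    argmax_hz <- sg$bin_freqs_hz[which.max(rowSums(sg$magnitudes^2))]
    expect_gte(argmax_hz, 100)
    expect_lte(argmax_hz, 400)
    expect_gte(band_energy_fraction(reb, 100, 400), 0.7)
  }
})

test_that("wind noise is low-frequency dominated; durations are exact", {
  wind <- gen_noise(kind = "wind", amplitude = 0.3, duration_s = 2, seed = 2)
  expect_length(wind$samples, 96000L)
  expect_gt(band_energy_fraction(wind, 0, 400),
            band_energy_fraction(wind, 400, 24000))
  for (kind in c("voice", "traffic", "crowd")) {
    nz <- gen_noise(kind = kind, amplitude = 0.2, duration_s = 0.5, seed = 9)
    expect_length(nz$samples, 24000L)
  }
})

test_that("an empty scene renders ambient only with empty truth", {
  spec <- scene_spec(1, data.frame(time_s = numeric(0), kind = character(0),
                                   amplitude = numeric(0)),
                     ambient_snr_db = 20, seed = 3)
  out <- render_scene(spec)
  expect_equal(nrow(out$truth), 0)
  expect_length(out$clip$samples, 48000L)
  expect_gt(stats::sd(out$clip$samples), 0)
})

test_that("scene ground truth marks the true waveform peak within 2 ms", {
  ev <- data.frame(time_s = c(0.5, 1.4), kind = c("impact", "rebound"),
                   amplitude = c(0.8, 0.3), player = "near")
  out <- render_scene(scene_spec(2, ev, ambient_snr_db = 40, seed = 6))
  fs <- out$clip$sample_rate
  for (i in seq_len(nrow(out$truth))) {
    lo <- round((out$truth$time_s[i] - 0.05) * fs)
    hi <- round((out$truth$time_s[i] + 0.05) * fs)
    local_pk <- (lo + which.max(abs(out$clip$samples[lo:hi])) - 1) / fs
    expect_lt(abs(local_pk - out$truth$time_s[i]), 0.002)
  }
})

test_that("far-player impacts are attenuated by the configured factor", {
  ev <- data.frame(time_s = c(0.5, 1.5), kind = "impact",
                   amplitude = c(0.8, 0.8), player = c("near", "far"))
  out <- render_scene(scene_spec(2.5, ev, ambient_snr_db = 60, seed = 8))
  expect_equal(out$truth$amplitude, c(0.8, 0.2))
})

test_that("a rally-1-like scene carries fifteen total hits", {
  sc <- scene_preset("rally1", seed = 4)
  out <- render_scene(sc)
  expect_equal(nrow(out$truth), 15)
  expect_equal(sum(out$truth$player == "near"), 8)
  near <- out$truth$time_s[out$truth$player == "near"]
  expect_equal(max(near) - min(near), 23.03, tolerance = 1e-9)
})

test_that("bank spec defaults total 1399 clips across the three classes", {
  spec <- bank_spec()
  expect_equal(c(spec$n_noise, spec$n_rebound, spec$n_impact),
               c(509L, 442L, 448L))
  expect_equal(spec$n_noise + spec$n_rebound + spec$n_impact, 1399L)
})

test_that("bank generation honors counts, clip length and determinism", {
  bank <- gen_sample_bank(bank_spec(n_noise = 8L, n_rebound = 7L,
                                    n_impact = 6L, seed = 31L))
  expect_length(bank$clips, 21L)
  expect_equal(as.vector(table(bank$labels)), c(8L, 7L, 6L))
  expect_true(all(vapply(bank$clips, function(cl)
    length(cl$samples), 0L) == 14400L))
  again <- gen_sample_bank(bank_spec(n_noise = 8L, n_rebound = 7L,
                                     n_impact = 6L, seed = 31L))
  expect_identical(lapply(bank$clips, `[[`, "samples"),
                   lapply(again$clips, `[[`, "samples"))
  alt_count <- bank_spec(n_noise = 500L, n_rebound = 450L, n_impact = 450L)
  expect_equal(alt_count$n_noise + alt_count$n_rebound + alt_count$n_impact,
               1400L)
})

test_that("banks roundtrip through disk", {
  bank <- gen_sample_bank(bank_spec(n_noise = 3L, n_rebound = 2L,
                                    n_impact = 2L, seed = 5L))
  dir <- withr::local_tempdir()
  write_bank(bank, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_bank(dir)
  expect_equal(as.character(back$labels), as.character(bank$labels))
  expect_lt(max(abs(back$clips[[1]]$samples - bank$clips[[1]]$samples)),
            1 / 32768 + 1e-12)
})
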