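# Synthetic generator: envelope structure, pause arithmetic, EEG forward
# model, determinism and fixture round-trips.

test_that("inserted pauses lengthen the envelope by exactly (n-1) * pause", {
  cfg <- sim_config(n_channels = 2, words_per_segment = 100, fs_env = 512,
                    seed = 5L)
  nat <- simulate_envelope(cfg, "natural", seed = 9L)
  sht <- simulate_envelope(cfg, "short", seed = 9L)
  lng <- simulate_envelope(cfg, "long", seed = 9L)
  extra_short <- length(sht$envelope$values) - length(nat$envelope$values)
  expect_equal(extra_short, 99 * round(0.25 * 512))
  extra_long <- length(lng$envelope$values) - length(sht$envelope$values)
  expect_equal(extra_long, 99 * round(0.25 * 512))
  # strictly increasing duration: natural < short < long
  expect_lt(length(nat$envelope$values), length(sht$envelope$values))
  expect_lt(length(sht$envelope$values), length(lng$envelope$values))
})

test_that("envelope is nonnegative and exactly zero inside pause intervals", {
  cfg <- tiny_config()
  sim <- simulate_envelope(cfg, "short", seed = 2L)
  v <- sim$envelope$values
  expect_gte(min(v), 0)
  fs <- sim$envelope$fs
  for (k in seq_len(nrow(sim$pause_intervals))) {
    i0 <- round(sim$pause_intervals$start_s[k] * fs) + 1
    i1 <- round(sim$pause_intervals$end_s[k] * fs)
    expect_true(all(v[i0:i1] == 0))
  }
  # and conversely: zero samples outside words are exactly the pauses
  in_pause <- logical(length(v))
  for (k in seq_len(nrow(sim$pause_intervals))) {
    i0 <- round(sim$pause_intervals$start_s[k] * fs) + 1
    i1 <- round(sim$pause_intervals$end_s[k] * fs)
    in_pause[i0:i1] <- TRUE
  }
  expect_true(all(v[!in_pause][1] >= 0))
})

test_that("envelope modulation spectrum peaks near the syllabic rate", {
  cfg <- sim_config(n_channels = 2, words_per_segment = 150,
                    syllable_rate_hz = 4.5, fs_env = 512, seed = 3L)
  sim <- simulate_envelope(cfg, "natural", seed = 3L)
  spec <- modulation_spectrum(sim$envelope, window_s = 4)
  peak_f <- spec$frequency[which.max(spec$power)]
  expect_gte(peak_f, 4)
  expect_lte(peak_f, 5)
})

test_that("EEG generation honours gains, kernels and determinism", {
  cfg <- tiny_config(snr_db = Inf, onset_gain = 0, sustained_gain = 0)
  sim <- simulate_envelope(cfg, "natural", seed = 1L)
  eeg0 <- simulate_eeg(sim, cfg, seed = 1L)
  expect_true(all(eeg0$eeg$data == 0))

  # determinism: same config and seed, bit-identical output
  cfg2 <- tiny_config()
  e1 <- simulate_eeg(sim, cfg2, seed = 8L)
  e2 <- simulate_eeg(sim, cfg2, seed = 8L)
  expect_identical(e1$eeg$data, e2$eeg$data)

  # unit-impulse kernel at lag 0, single channel, sustained only:
  # the clean EEG equals the (gain-scaled) envelope
  cfg3 <- sim_config(n_channels = 1, words_per_segment = 20, fs_env = 512,
                     fs_eeg = 512, snr_db = Inf, onset_gain = 0,
                     sustained_gain = 1, sustained_latency_ms = 0,
                     sustained_width_ms = 1e-9, seed = 4L)
  sim3 <- simulate_envelope(cfg3, "natural", seed = 4L)
  e3 <- simulate_eeg(sim3, cfg3, seed = 4L)
  gain <- e3$ground_truth$gain_sustained[1]
  expect_equal(as.numeric(e3$eeg$data[1, ]), gain * sim3$envelope$values,
               tolerance = 1e-10)
})

test_that("empirical per-channel SNR matches the requested level within 1 dB", {
  cfg <- tiny_config(snr_db = 3)
  sim <- simulate_envelope(cfg, "natural", seed = 6L)
  out <- simulate_eeg(sim, cfg, seed = 6L)
  clean <- out$ground_truth$clean_eeg
  noise <- out$eeg$data - clean
  snr_emp <- 10 * log10(rowMeans(clean^2) / rowMeans(noise^2))
  expect_true(all(abs(snr_emp - 3) < 1))
})

test_that("noise spectrum falls off like 1/f", {
  set.seed(10)
  x <- pink_noise(2^14, exponent = 1)
  ps <- welch_psd(x, fs = 256, window_s = 2)
  lowband <- mean(ps$power[ps$frequency >= 1 & ps$frequency <= 4])
  highband <- mean(ps$power[ps$frequency >= 32 & ps$frequency <= 64])
  # ~15 dB/decade expected between band centres (factor ~16 in frequency)
  expect_gt(lowband / highband, 5)
})

test_that("pause-removed modulation spectra coincide across conditions", {
  cfg <- tiny_config()
  specs <- lapply(c("natural", "short", "long"), function(cond) {
    sim <- simulate_envelope(cfg, cond, seed = 21L)
    modulation_spectrum(sim$envelope, remove_pauses = TRUE,
                        pause_intervals = sim$pause_intervals)
  })
  expect_equal(specs[[1]], specs[[2]], tolerance = 1e-12)
  expect_equal(specs[[2]], specs[[3]], tolerance = 1e-12)
})

test_that("fixtures round-trip through the readers", {
  cfg <- sim_config(n_subjects = 1, n_segments_per_condition = 2,
                    n_channels = 2, words_per_segment = 10, fs_env = 256,
                    fs_eeg = 256, snr_db = 0, seed = 11L)
  rec <- simulate_recording(cfg, 1, 1, "short")
  dir <- withr::local_tempdir()
  manifest <- write_fixture(rec, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "envelope.wav")))
  expect_equal(manifest$condition, "short")

  back <- read_fixture(dir)
  # envelope within float32 WAV precision
  expect_equal(back$envelope$values, rec$envelope$values, tolerance = 1e-6)
  expect_equal(back$envelope$fs, rec$envelope$fs)
  # EEG at full double precision through the TSV
  expect_equal(back$eeg$data, rec$eeg$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$word_boundaries$onset_s, rec$word_boundaries$onset_s)

  # the manifest reproduces the generator output
  cfg2 <- do.call(sim_config, manifest$config[names(manifest$config) %in%
                                                names(formals(sim_config))])
  rec2 <- simulate_recording(cfg2, manifest$subject, manifest$segment,
                             manifest$condition)
  expect_identical(rec2$eeg$data, rec$eeg$data)

  # degenerate input errors instead of writing empty files
  empty <- rec
  empty$envelope$values <- numeric(0)
  expect_error(write_fixture(empty, withr::local_tempdir()), "empty")
})

test_that("per-recording seed streams are reproducible and distinct", {
  s1 <- stream_seed(42, 1, 1, "natural")
  s2 <- stream_seed(42, 1, 1, "short")
  s3 <- stream_seed(42, 2, 1, "natural")
  expect_identical(s1, stream_seed(42, 1, 1, "natural"))
  expect_true(length(unique(c(s1, s2, s3))) == 3)
  expect_true(all(c(s1, s2, s3) >= 0 & c(s1, s2, s3) < 2^31))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_segments_per_condition = 1), "leave-one-out")
  expect_error(sim_config(word_duration_mean = -1), "positive")
  expect_error(sim_config(fs_env = 0), "positive")
})
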