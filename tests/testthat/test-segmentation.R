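# Pause detection and onset/non-onset labelling.

test_that("degenerate envelopes produce all-pause or no-pause masks", {
  env0 <- envelope_series(numeric(256), 128)
  m0 <- detect_pauses(env0)
  expect_true(all(m0$labels == "pause"))

  env1 <- envelope_series(rep(1, 256) + 0.1 * sin(1:256), 128)
  m1 <- detect_pauses(env1)
  expect_true(all(m1$labels != "pause"))
})

test_that("detected pauses match generator ground truth within one sample", {
  cfg <- tiny_config()
  sim <- simulate_envelope(cfg, "short", seed = 31L)
  bb <- downsample_envelope(sim$envelope, 128)
  det <- detect_pauses(bb, threshold_frac = 0.01, min_pause_ms = 100)
  truth <- mask_from_ground_truth(sim$pause_intervals, length(bb$values), 128)

  runs <- function(labels) {
    r <- rle(labels == "pause")
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    cbind(start = s[r$values], end = e[r$values])
  }
  rd <- runs(det$labels)
  rt <- runs(truth$labels)
  # only ground-truth pauses long enough to be detectable are compared
  min_run <- round(0.100 * 128)
  rt <- rt[(rt[, "end"] - rt[, "start"] + 1) >= min_run + 2, , drop = FALSE]
  for (i in seq_len(nrow(rt))) {
    j <- which.min(abs(rd[, "start"] - rt[i, "start"]))
    expect_lte(abs(rd[j, "start"] - rt[i, "start"]), 2)
    expect_lte(abs(rd[j, "end"] - rt[i, "end"]), 2)
  }
})

test_that("labels partition the axis and onset runs follow pauses", {
  cfg <- tiny_config()
  sim <- simulate_envelope(cfg, "long", seed = 32L)
  bb <- downsample_envelope(sim$envelope, 128)
  mask <- detect_pauses(bb)
  tab <- table(factor(mask$labels, c("pause", "onset", "non_onset")))
  expect_equal(sum(tab), length(bb$values))

  # every onset run starts right after a pause sample and lasts <= 19 samples
  r <- rle(mask$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onset_runs <- which(r$values == "onset")
  for (k in onset_runs) {
    expect_lte(r$lengths[k], round(0.150 * 128))
    if (starts[k] > 1) expect_equal(r$values[k - 1], "pause")
  }
})

test_that("raising the detection threshold never shrinks the pause set", {
  cfg <- tiny_config()
  sim <- simulate_envelope(cfg, "short", seed = 33L)
  bb <- downsample_envelope(sim$envelope, 128)
  fr <- c(0.005, 0.01, 0.05, 0.2)
  pause_sets <- lapply(fr, function(f) {
    detect_pauses(bb, threshold_frac = f)$labels == "pause"
  })
  for (i in seq_along(fr)[-1]) {
    expect_true(all(pause_sets[[i - 1]] <= pause_sets[[i]]))
  }
})

test_that("features carve the expected valid-sample sets", {
  # 10 pauses each followed by >= 150 ms of speech at 128 Hz
  fs <- 128
  piece <- c(rep(0, 20), rep(1, 60))
  env_bb <- envelope_series(rep(piece, 10), fs)
  mask <- detect_pauses(env_bb, min_pause_ms = 100)
  env_band <- envelope_series(rnorm(length(env_bb$values)), fs, band = "delta")

  f_full <- build_feature(env_band, mask, "full")
  expect_equal(sum(f_full$mask), length(env_band$values))

  f_on <- build_feature(env_band, mask, "onsets")
  expect_equal(sum(f_on$mask), 10 * round(0.150 * 128))

  f_non <- build_feature(env_band, mask, "non_onsets")
  # partition: onsets, non-onsets and pauses tile the axis with no overlap
  pauses <- mask$labels == "pause"
  expect_equal(sum(f_on$mask) + sum(f_non$mask) + sum(pauses),
               length(env_band$values))
  expect_true(all(!(f_on$mask & f_non$mask)))
  expect_true(all(!(f_on$mask & pauses)))

  expect_error(build_feature(envelope_series(rnorm(10), fs, band = "delta"),
                             mask, "full"), "length")
})

test_that("pause removal drops exactly the pause samples from both series", {
  fs <- 128
  piece <- c(rep(0, 20), rep(1, 80))
  env_bb <- envelope_series(rep(piece, 10), fs)
  mask <- detect_pauses(env_bb, min_pause_ms = 100)
  n <- length(env_bb$values)
  eeg <- eeg_recording(matrix(rnorm(2 * n), 2, n), fs)
  env_band <- envelope_series(rnorm(n), fs, band = "delta")

  out <- remove_pause_samples(env_band, eeg, mask)
  n_pause <- sum(mask$labels == "pause")
  expect_equal(length(out$envelope$values), n - n_pause)
  expect_equal(ncol(out$eeg$data), n - n_pause)
  keep <- mask$labels != "pause"
  expect_equal(out$envelope$values, env_band$values[keep])
  expect_equal(out$eeg$data, eeg$data[, keep], ignore_attr = TRUE)

  # no pauses: identity on both
  all_speech <- segment_mask(rep("non_onset", n), fs)
  out2 <- remove_pause_samples(env_band, eeg, all_speech)
  expect_equal(out2$envelope$values, env_band$values)
  expect_equal(out2$eeg$data, eeg$data, ignore_attr = TRUE)
})

test_that("amplitude histograms count valid samples per label", {
  cfg <- tiny_config()
  sim <- simulate_envelope(cfg, "short", seed = 34L)
  band <- bandlimit_envelope(sim$envelope, "delta", 128)
  n <- length(band$values)
  mask <- mask_from_ground_truth(sim$pause_intervals, n, 128)

  h <- amplitude_histogram(band, mask)
  expect_equal(sum(h$count[h$label == "onset"]), attr(h, "n_onset"))
  expect_equal(sum(h$count[h$label == "non_onset"]), attr(h, "n_non_onset"))
  # non-onsets cover more samples than onsets in running speech
  expect_gt(attr(h, "n_non_onset"), attr(h, "n_onset"))
  expect_false(attr(h, "flagged"))

  degenerate <- segment_mask(rep("non_onset", n), 128)
  expect_warning(h2 <- amplitude_histogram(band, degenerate), "empty")
  expect_true(attr(h2, "flagged"))
  expect_equal(sum(h2$count[h2$label == "onset"]), 0)
})
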