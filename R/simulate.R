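# Synthetic speech-envelope / EEG generator. The generator is the package's
# test bed: it produces envelopes with the word/pause temporal structure of
# the stimulus manipulation (silent pauses of 0 / 250 / 500 ms inserted
# between words) and multichannel EEG driven by known onset and sustained
# response kernels plus 1/f background noise.

#' Simulation configuration
#'
#' Parameters of the synthetic speech/EEG generator. Defaults mirror the
#' study design being emulated: 16 subjects, 32 EEG channels, 4 speech
#' segments per pause condition, syllabic modulation at 4.5 Hz, inserted
#' pauses of 0 ms (natural), 250 ms (short) or 500 ms (long), EEG acquisition
#' at 4092 Hz. `fs_env` is the rate at which the envelope is synthesised
#' (the envelope carries no energy above a few tens of Hz, so it need not be
#' synthesised at the audio rate).
#'
#' @param n_subjects number of simulated subjects.
#' @param n_segments_per_condition speech segments per condition (>= 2; the
#'   leave-one-out cross-validation needs at least two).
#' @param n_channels number of EEG channels.
#' @param words_per_segment words in each speech segment.
#' @param fs_audio audio rate in Hz (used when writing WAV fixtures).
#' @param fs_env envelope synthesis rate in Hz.
#' @param fs_eeg EEG rate in Hz.
#' @param word_duration_mean,word_duration_sd lognormal word-duration
#'   parameters, seconds.
#' @param natural_pause_mean,natural_pause_sd lognormal natural-pause
#'   parameters, seconds.
#' @param syllable_rate_hz syllabic modulation rate of the envelope, Hz.
#' @param attack_ms raised-cosine attack/decay of each word, milliseconds.
#' @param onset_latency_ms,onset_width_ms onset-response kernel peak latency
#'   and FWHM, milliseconds.
#' @param sustained_latency_ms,sustained_width_ms sustained-response kernel
#'   peak latency and FWHM, milliseconds.
#' @param onset_gain,sustained_gain dimensionless gains of the two response
#'   pathways.
#' @param onset_recovery_tau_s recovery time constant (seconds) of the
#'   onset response: the response to an onset following a silent gap of
#'   duration `g` is scaled by `1 - exp(-g / tau)`, the saturating
#'   enhancement of auditory late responses by longer inter-stimulus
#'   silence. `0` disables the mechanism (constant onset amplitude).
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param snr_db per-channel signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param seed master RNG seed; every recording derives its own stream from
#'   it (see [stream_seed()]).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16,
                       n_segments_per_condition = 4,
                       n_channels = 32,
                       words_per_segment = 350,
                       fs_audio = 44100,
                       fs_env = 512,
                       fs_eeg = 4092,
                       word_duration_mean = 0.35,
                       word_duration_sd = 0.10,
                       natural_pause_mean = 0.08,
                       natural_pause_sd = 0.03,
                       syllable_rate_hz = 4.5,
                       attack_ms = 30,
                       onset_latency_ms = 100,
                       onset_width_ms = 80,
                       sustained_latency_ms = 150,
                       sustained_width_ms = 120,
                       onset_gain = 1,
                       sustained_gain = 1,
                       onset_recovery_tau_s = 1,
                       noise_exponent = 1,
                       snr_db = 0,
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects,
    n_segments_per_condition = n_segments_per_condition,
    n_channels = n_channels,
    words_per_segment = words_per_segment,
    fs_audio = fs_audio, fs_env = fs_env, fs_eeg = fs_eeg,
    word_duration_mean = word_duration_mean,
    word_duration_sd = word_duration_sd,
    natural_pause_mean = natural_pause_mean,
    natural_pause_sd = natural_pause_sd,
    syllable_rate_hz = syllable_rate_hz,
    attack_ms = attack_ms,
    onset_latency_ms = onset_latency_ms, onset_width_ms = onset_width_ms,
    sustained_latency_ms = sustained_latency_ms,
    sustained_width_ms = sustained_width_ms,
    onset_gain = onset_gain, sustained_gain = sustained_gain,
    onset_recovery_tau_s = onset_recovery_tau_s,
    noise_exponent = noise_exponent, snr_db = snr_db,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_subjects", "n_segments_per_condition", "n_channels",
           "words_per_segment", "fs_audio", "fs_env", "fs_eeg",
           "word_duration_mean", "word_duration_sd", "natural_pause_mean",
           "syllable_rate_hz")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("configuration error: `", f, "` must be positive")
    }
  }
  if (cfg$n_segments_per_condition < 2) {
    stop("configuration error: need >= 2 segments per condition (leave-one-out)")
  }
  invisible(cfg)
}

# Inserted pause per condition, seconds.
inserted_pause_s <- function(condition) {
  switch(condition, natural = 0, short = 0.25, long = 0.5,
         stop("unknown condition: ", condition))
}

condition_index <- function(condition) {
  match(condition, c("natural", "short", "long", "other"))
}

#' Derive an RNG stream seed for one recording
#'
#' Deterministic counter scheme mapping (master seed, subject, segment,
#' condition) to an independent stream seed, so every recording's noise is
#' reproducible in isolation.
#'
#' @param master master seed (integer).
#' @param subject,segment 1-based indices.
#' @param condition condition label.
#' @return integer seed below 2^31.
#' @export
stream_seed <- function(master, subject = 1L, segment = 1L,
                        condition = "natural") {
  m <- 2147483563
  s <- (as.double(master) * 69069 +
        subject * 1299709 +
        segment * 104729 +
        condition_index(condition) * 7919) %% m
  as.integer(s)
}

# lognormal parameters from arithmetic mean / sd
lnorm_pars <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# One word-shaped envelope burst: rectified sinusoid at the syllabic rate
# under a raised-cosine attack/decay amplitude contour.
word_burst <- function(n, fs, syllable_rate_hz, attack_ms, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  syll <- abs(sin(pi * syllable_rate_hz * t))
  contour <- rep(1, n)
  na <- min(round(attack_ms / 1000 * fs), floor(n / 2))
  if (na > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(na)) / na))
    contour[seq_len(na)] <- ramp
    contour[(n - na + 1):n] <- rev(ramp)
  }
  amp * syll * contour
}

#' Simulate a speech-like broadband envelope
#'
#' Draws a word sequence (lognormal word durations and natural pause
#' durations, small word-level amplitude variation), renders each word as a
#' syllabic-rate burst, and concatenates words separated by silence. For the
#' `short` / `long` conditions an additional silent gap of 250 / 500 ms is
#' spliced into each of the `n_words - 1` between-word gaps; the word
#' waveforms themselves are identical across conditions for the same seed,
#' so pause-excised envelopes coincide exactly.
#'
#' @param config a [sim_config()].
#' @param condition `"natural"`, `"short"` or `"long"`.
#' @param seed RNG seed for this segment (defaults to the config master seed).
#' @return list with elements `envelope` (broadband [envelope_series()] at
#'   `config$fs_env`), `word_boundaries` (tibble `word_index`, `onset_s`,
#'   `offset_s`), and `pause_intervals` (tibble `start_s`, `end_s`).
#' @export
simulate_envelope <- function(config, condition = c("natural", "short", "long"),
                              seed = config$seed) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  fs <- config$fs_env
  nw <- config$words_per_segment
  withr::local_seed(seed)

  wp <- lnorm_pars(config$word_duration_mean, config$word_duration_sd)
  pp <- lnorm_pars(config$natural_pause_mean, config$natural_pause_sd)
  word_dur <- stats::rlnorm(nw, wp$meanlog, wp$sdlog)
  gap_dur <- stats::rlnorm(max(nw - 1, 0), pp$meanlog, pp$sdlog)
  amps <- pmax(stats::rnorm(nw, 1, 0.1), 0.5)

  word_n <- pmax(round(word_dur * fs), 2L)
  gap_n <- round(gap_dur * fs) + round(inserted_pause_s(condition) * fs)

  pieces <- vector("list", 2 * nw - 1)
  onset_samp <- integer(nw)
  offset_samp <- integer(nw)
  pause_start <- integer(max(nw - 1, 0))
  pause_end <- integer(max(nw - 1, 0))
  pos <- 0L
  for (i in seq_len(nw)) {
    onset_samp[i] <- pos
    pieces[[2 * i - 1]] <- word_burst(word_n[i], fs, config$syllable_rate_hz,
                                      config$attack_ms, amps[i])
    pos <- pos + word_n[i]
    offset_samp[i] <- pos
    if (i < nw) {
      pieces[[2 * i]] <- numeric(gap_n[i])
      pause_start[i] <- pos
      pos <- pos + gap_n[i]
      pause_end[i] <- pos
    }
  }
  values <- unlist(pieces)

  list(
    envelope = envelope_series(values, fs, band = "broadband"),
    word_boundaries = tibble::tibble(
      word_index = seq_len(nw),
      onset_s = onset_samp / fs,
      offset_s = offset_samp / fs
    ),
    pause_intervals = tibble::tibble(
      start_s = pause_start / fs,
      end_s = pause_end / fs
    )
  )
}

# Causal Gaussian-bump response kernel sampled at fs: peaks at `latency_ms`,
# full width at half maximum `width_ms`.
response_kernel <- function(fs, latency_ms, width_ms) {
  sigma <- width_ms / 1000 / 2.355
  lat <- latency_ms / 1000
  t <- seq(0, lat + 4 * sigma, by = 1 / fs)
  exp(-0.5 * ((t - lat) / sigma)^2)
}

# Biphasic onset-response kernel emulating the N1-P2 complex of the
# auditory late response: a negative deflection at `latency_ms` followed by
# a positive one 80 ms later and slightly wider. The N1 width is taken from
# `width_ms` scaled to its conventional ~50 ms at the 80 ms default.
alr_kernel <- function(fs, latency_ms, width_ms) {
  g <- function(lat_ms, wid_ms) {
    sigma <- wid_ms / 1000 / 2.355
    lat <- lat_ms / 1000
    t <- seq(0, (latency_ms + 80) / 1000 + 0.25, by = 1 / fs)
    exp(-0.5 * ((t - lat) / sigma)^2)
  }
  -g(latency_ms, width_ms * 0.625) + 0.9 * g(latency_ms + 80, width_ms * 0.875)
}

# indicator of the first `window_ms` of speech following each pause interval
onset_indicator <- function(n, fs, pause_intervals, window_ms = 150) {
  onset_weights(n, fs, pause_intervals, window_ms, recovery_tau_s = 0) > 0
}

# per-sample onset-drive weights: the onset window after each pause carries
# weight 1 - exp(-gap / tau), the saturating recovery of the auditory late
# response with longer preceding silence (tau = 0 gives constant weight 1)
onset_weights <- function(n, fs, pause_intervals, window_ms = 150,
                          recovery_tau_s = 1) {
  w <- numeric(n)
  if (!nrow(pause_intervals)) return(w)
  wlen <- round(window_ms / 1000 * fs)
  gap <- pause_intervals$end_s - pause_intervals$start_s
  amp <- if (recovery_tau_s > 0) 1 - exp(-gap / recovery_tau_s) else rep(1, length(gap))
  for (k in seq_len(nrow(pause_intervals))) {
    s0 <- round(pause_intervals$end_s[k] * fs) + 1L
    if (s0 > n) next
    w[s0:min(s0 + wlen - 1L, n)] <- amp[k]
  }
  w
}

#' Simulate multichannel EEG from an envelope
#'
#' Forward generative model: each channel is
#' `onset_gain * gain_on[ch] * (k_on (*) onset_drive) +
#'  sustained_gain * gain_sus[ch] * (k_sus (*) envelope) + noise`,
#' where `onset_drive` is the envelope restricted to the first 150 ms of
#' speech after each pause (zero elsewhere), scaled per onset by the
#' silence-recovery factor `1 - exp(-gap / onset_recovery_tau_s)`. The
#' onset kernel `k_on` is a biphasic N1-P2 (auditory late response) shape;
#' the sustained kernel `k_sus` is a causal Gaussian bump. Per-channel
#' gains are drawn once per `gain_seed`, and the noise is Gaussian
#' `1/f^a`, scaled so each channel's clean-signal-to-noise power ratio
#' equals `snr_db` exactly. Deterministic given the seed.
#'
#' @param env_sim output of [simulate_envelope()] (envelope plus ground-truth
#'   intervals).
#' @param config a [sim_config()].
#' @param seed RNG seed for this recording's noise.
#' @param gain_seed RNG seed for the per-channel gain maps (pass the same
#'   value across a subject's recordings to keep their "head" fixed).
#' @param subject_id,segment_id,condition metadata stamped on the output.
#' @return list with `eeg` (an [eeg_recording()] at `config$fs_eeg`) and
#'   `ground_truth` (kernels, per-channel gains, boundaries, pause intervals,
#'   onset indicator, clean EEG).
#' @export
simulate_eeg <- function(env_sim, config, seed = config$seed,
                         gain_seed = seed,
                         subject_id = "S01", segment_id = 1L,
                         condition = c("natural", "short", "long")) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  env <- env_sim$envelope
  fs <- config$fs_eeg
  x <- if (env$fs == fs) env$values else resample_signal(env$values, env$fs, fs)
  x[x < 0] <- 0
  n <- length(x)

  # per-channel gains are a property of the simulated head: drawn from their
  # own stream so they stay fixed across a subject's segments and conditions
  gains <- withr::with_seed(gain_seed, list(
    on = pmax(stats::rnorm(config$n_channels, 1, 0.3), 0.2),
    sus = pmax(stats::rnorm(config$n_channels, 1, 0.3), 0.2)
  ))
  gain_on <- gains$on
  gain_sus <- gains$sus

  withr::local_seed(seed)

  on_w <- onset_weights(n, fs, env_sim$pause_intervals, 150,
                        config$onset_recovery_tau_s)
  onset_drive <- x * on_w

  k_on <- alr_kernel(fs, config$onset_latency_ms, config$onset_width_ms)
  k_sus <- response_kernel(fs, config$sustained_latency_ms,
                           config$sustained_width_ms)

  conv_causal <- function(sig, kern) {
    fft_conv(sig, kern)[seq_len(n)]
  }
  resp_on <- if (config$onset_gain != 0) conv_causal(onset_drive, k_on) else numeric(n)
  resp_sus <- if (config$sustained_gain != 0) conv_causal(x, k_sus) else numeric(n)

  clean <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    clean[ch, ] <- config$onset_gain * gain_on[ch] * resp_on +
      config$sustained_gain * gain_sus[ch] * resp_sus
  }

  data <- clean
  if (is.finite(config$snr_db)) {
    for (ch in seq_len(config$n_channels)) {
      nz <- pink_noise(n, config$noise_exponent)
      p_sig <- mean(clean[ch, ]^2)
      p_target <- if (p_sig > 0) p_sig / 10^(config$snr_db / 10) else 1
      nz <- nz * sqrt(p_target / mean(nz^2))
      data[ch, ] <- clean[ch, ] + nz
    }
  }

  list(
    eeg = eeg_recording(data, fs, subject_id = subject_id,
                        segment_id = segment_id, condition = condition),
    ground_truth = list(
      kernel_onset = k_on, kernel_sustained = k_sus,
      gain_onset = gain_on, gain_sustained = gain_sus,
      word_boundaries = env_sim$word_boundaries,
      pause_intervals = env_sim$pause_intervals,
      onset_weights = on_w,
      clean_eeg = clean
    )
  )
}

#' Simulate one recording (envelope + EEG) for a subject/segment/condition
#'
#' Convenience wrapper deriving the recording's RNG stream from the master
#' seed via [stream_seed()].
#'
#' @inheritParams simulate_eeg
#' @param subject,segment 1-based indices.
#' @export
simulate_recording <- function(config, subject = 1L, segment = 1L,
                               condition = "natural") {
  # the word sequence is shared across conditions: seed it from the segment
  # only, so inserted pauses are the only difference between conditions
  sd_words <- stream_seed(config$seed, subject, segment, "natural")
  # noise stream is condition-specific and offset from the envelope stream
  sd_eeg <- (stream_seed(config$seed, subject, segment, condition) + 9973L) %%
    2147483563L
  sd_gain <- stream_seed(config$seed, subject, 0L, "natural")
  env_sim <- simulate_envelope(config, condition, seed = sd_words)
  eeg_sim <- simulate_eeg(env_sim, config, seed = sd_eeg, gain_seed = sd_gain,
                          subject_id = sprintf("S%02d", subject),
                          segment_id = segment, condition = condition)
  c(env_sim, eeg_sim, list(condition = condition, subject = subject,
                           segment = segment))
}

#' Simulate a full dataset as a tibble
#'
#' One row per (subject, condition, segment), with list-columns holding the
#' envelope, EEG, ground truth and word/pause annotations.
#'
#' @param config a [sim_config()].
#' @param conditions conditions to simulate.
#' @param subjects subject indices (default all in `config`).
#' @return tibble with list-columns `envelope`, `eeg`, `ground_truth`,
#'   `word_boundaries`, `pause_intervals`.
#' @export
simulate_dataset <- function(config,
                             conditions = c("natural", "short", "long"),
                             subjects = seq_len(config$n_subjects)) {
  grid <- tidyr::expand_grid(
    subject = subjects,
    condition = conditions,
    segment = seq_len(config$n_segments_per_condition)
  )
  recs <- purrr::pmap(grid, function(subject, condition, segment) {
    simulate_recording(config, subject, segment, condition)
  })
  dplyr::mutate(
    grid,
    envelope = purrr::map(recs, "envelope"),
    eeg = purrr::map(recs, "eeg"),
    ground_truth = purrr::map(recs, "ground_truth"),
    word_boundaries = purrr::map(recs, "word_boundaries"),
    pause_intervals = purrr::map(recs, "pause_intervals")
  )
}
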