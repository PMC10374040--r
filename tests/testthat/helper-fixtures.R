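# Shared in-code fixtures. Everything is generated at test time; sizes are
# kept small so the whole suite runs quickly.

# a compact generator configuration for fast end-to-end tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 1, n_segments_per_condition = 4, n_channels = 3,
         words_per_segment = 60, fs_env = 512, fs_eeg = 512, snr_db = 5,
         seed = 42L),
    list(...)
  )
  do.call(sim_config, args)
}

# brute-force decoder oracle: forms the centred normal equations and solves
# them by explicit matrix inversion (dense algebra, independent of the
# package's Cholesky path)
oracle_decoder <- function(design, target, lambda, M, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(target))
  X <- design[mask, , drop = FALSE]
  y <- target[mask]
  X <- sweep(X, 2, colMeans(X))
  y <- y - mean(y)
  as.numeric(solve(crossprod(X) + lambda * M) %*% crossprod(X, y))
}

# random decoder test instance (returns design, target, M, spec)
random_decoder_instance <- function(n = 200, n_channels = 2, n_lags = 4,
                                    fs = 128) {
  eeg_mat <- matrix(stats::rnorm(n_channels * n), n_channels, n)
  spec <- lag_spec(0, (n_lags - 1) / fs * 1000, fs)
  stopifnot(spec$n_lags == n_lags)
  design <- build_lagged_design(eeg_mat, spec)
  target <- stats::rnorm(n)
  M <- build_regularizer(spec, n_channels)
  list(design = design, target = target, M = M, spec = spec,
       n_channels = n_channels)
}

# segments list (eeg + band-limited envelope + mask) for one condition of a
# simulated subject, preprocessed to the analysis rate
make_cell_segments <- function(config, condition = "natural", band = "delta",
                               subject = 1L, fs_out = 128,
                               mask_source = "ground_truth") {
  lapply(seq_len(config$n_segments_per_condition), function(seg_i) {
    rec <- simulate_recording(config, subject, seg_i, condition)
    eeg <- preprocess_eeg(rec$eeg, band, fs_out)
    env <- bandlimit_envelope(rec$envelope, band, fs_out)
    n <- min(length(env$values), ncol(eeg$data))
    mask <- if (mask_source == "ground_truth") {
      mask_from_ground_truth(rec$pause_intervals, n, fs_out)
    } else {
      bb <- downsample_envelope(rec$envelope, fs_out)
      detect_pauses(bb)
    }
    list(eeg = eeg, envelope = env, mask = mask)
  })
}
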