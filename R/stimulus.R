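# Stimulus manipulation and envelope extraction.

#' Insert silent pauses between words
#'
#' Splices `pause_s` seconds of exact digital silence after each word offset
#' except the last (`n_words - 1` insertions), shifting all later word
#' boundaries accordingly. Optionally applies a short raised-cosine fade-out
#' before and fade-in after each splice point to avoid clicks in real audio;
#' with `fade_ms = 0` the operation is sample-exact and the output duration
#' is `input + (n_words - 1) * round(pause_s * fs)` samples.
#'
#' @param audio an [annotated_audio()].
#' @param pause_s pause duration to insert, seconds (>= 0).
#' @param fade_ms raised-cosine fade at each splice point, milliseconds.
#' @param condition condition label for the output (default inferred:
#'   0 s -> unchanged label, 0.25 -> "short", 0.5 -> "long", else "other").
#' @return an [annotated_audio()] with shifted boundaries.
#' @export
insert_pauses <- function(audio, pause_s, fade_ms = 0, condition = NULL) {
  stopifnot(inherits(audio, "annotated_audio"))
  if (pause_s < 0) stop("`pause_s` must be >= 0")
  wb <- audio$word_boundaries
  if (!nrow(wb)) stop("annotation error: no word boundaries")
  if (pause_s == 0) return(audio)
  fs <- audio$fs
  gap_n <- round(pause_s * fs)
  nw <- nrow(wb)

  x <- audio$samples
  if (fade_ms > 0) {
    nf <- round(fade_ms / 1000 * fs)
    ramp <- 0.5 * (1 + cos(pi * seq_len(nf) / nf)) # 1 -> 0
    for (i in seq_len(nw)) {
      off <- round(wb$offset_s[i] * fs)
      idx <- seq(max(off - nf + 1, 1), off)
      x[idx] <- x[idx] * ramp[seq_along(idx) + (nf - length(idx))]
      on <- round(wb$onset_s[i] * fs) + 1L
      idx <- seq(on, min(on + nf - 1, length(x)))
      x[idx] <- x[idx] * rev(ramp)[seq_along(idx)]
    }
  }

  cut_pts <- round(wb$offset_s[-nw] * fs) # splice after these samples
  pieces <- vector("list", 2 * nw - 1)
  prev <- 0L
  for (i in seq_len(nw - 1)) {
    pieces[[2 * i - 1]] <- x[(prev + 1L):cut_pts[i]]
    pieces[[2 * i]] <- numeric(gap_n)
    prev <- cut_pts[i]
  }
  pieces[[2 * nw - 1]] <- x[(prev + 1L):length(x)]

  shift <- c(0, seq_len(nw - 1)) * gap_n / fs
  wb_new <- tibble::tibble(
    onset_s = wb$onset_s + shift,
    offset_s = wb$offset_s + shift
  )
  if ("token" %in% names(wb)) wb_new$token <- wb$token
  if ("word_index" %in% names(wb)) {
    wb_new <- tibble::add_column(wb_new, word_index = wb$word_index,
                                 .before = 1)
  }
  if (is.null(condition)) {
    condition <- if (isTRUE(all.equal(pause_s, 0.25))) "short"
      else if (isTRUE(all.equal(pause_s, 0.5))) "long"
      else "other"
  }
  annotated_audio(unlist(pieces), fs, wb_new, condition = condition)
}

#' Extract the broadband amplitude envelope
#'
#' Magnitude of the analytic (Hilbert) signal of the waveform, at the native
#' sampling rate. Sign-invariant and nonnegative.
#'
#' @param audio an [annotated_audio()] or a numeric waveform.
#' @param fs sampling rate, required when `audio` is a bare vector.
#' @return a broadband [envelope_series()].
#' @export
extract_envelope <- function(audio, fs = NULL) {
  if (inherits(audio, "annotated_audio")) {
    x <- audio$samples
    fs <- audio$fs
  } else {
    x <- as.numeric(audio)
    if (is.null(fs)) stop("`fs` required for a bare waveform")
  }
  if (!length(x)) stop("empty waveform")
  envelope_series(Mod(analytic_signal(x)), fs, band = "broadband")
}

#' Band-limit an envelope and bring it to the analysis rate
#'
#' Zero-phase FIR band-pass (delta 1-4 Hz or theta 4-8 Hz, same filter
#' contract as [bandpass_eeg()]) applied at the envelope's native rate,
#' followed by resampling to `fs_out`.
#'
#' @param env a broadband [envelope_series()].
#' @param band `"delta"` or `"theta"`.
#' @param fs_out output rate, Hz (default 128).
#' @return a band-limited [envelope_series()] at `fs_out`.
#' @export
bandlimit_envelope <- function(env, band = c("delta", "theta"), fs_out = 128) {
  band <- match.arg(band)
  stopifnot(inherits(env, "envelope_series"))
  if (env$band != "broadband") stop("input envelope must be broadband")
  edges <- band_edges(band)
  if (edges[2] >= fs_out / 2) stop("band edge at or above output Nyquist")
  taps <- design_fir_bandpass(env$fs, edges[1], edges[2])
  if (length(env$values) < length(taps)) {
    stop("envelope shorter than the filter")
  }
  y <- apply_fir_zerophase(env$values, taps)
  y <- resample_signal(y, env$fs, fs_out)
  envelope_series(y, fs_out, band = band)
}

band_edges <- function(band) {
  switch(band, delta = c(1, 4), theta = c(4, 8),
         stop("unknown band: ", band))
}

#' Downsample a broadband envelope to the analysis rate
#'
#' Anti-aliased rate conversion of the (nonnegative) broadband envelope,
#' used for pause detection at the analysis rate. Small negative ringing
#' introduced by resampling is clipped at zero.
#'
#' @param env broadband [envelope_series()].
#' @param fs_out target rate, Hz.
#' @export
downsample_envelope <- function(env, fs_out = 128) {
  stopifnot(inherits(env, "envelope_series"), env$band == "broadband")
  y <- resample_signal(env$values, env$fs, fs_out)
  envelope_series(pmax(y, 0), fs_out, band = "broadband")
}

#' Modulation spectrum of an envelope
#'
#' Averaged-periodogram (Welch) estimate of the envelope power spectrum on
#' 0-32 Hz, normalised to unit total power (`sum(power) * df = 1`).
#' With `remove_pauses = TRUE` the pause intervals are excised and the
#' remaining speech concatenated before the spectrum is computed, which
#' makes spectra of the same word sequence identical across pause
#' conditions.
#'
#' @param env broadband [envelope_series()].
#' @param remove_pauses excise pause intervals first?
#' @param pause_intervals tibble with `start_s`, `end_s` (required when
#'   `remove_pauses = TRUE`).
#' @param window_s Welch window length, seconds.
#' @param f_max upper frequency of the returned grid, Hz.
#' @return tibble with columns `frequency` and `power`.
#' @export
modulation_spectrum <- function(env, remove_pauses = FALSE,
                                pause_intervals = NULL, window_s = 4,
                                f_max = 32) {
  stopifnot(inherits(env, "envelope_series"))
  x <- env$values
  if (remove_pauses) {
    if (is.null(pause_intervals)) stop("pause intervals required")
    keep <- rep(TRUE, length(x))
    for (k in seq_len(nrow(pause_intervals))) {
      i0 <- round(pause_intervals$start_s[k] * env$fs) + 1L
      i1 <- round(pause_intervals$end_s[k] * env$fs)
      if (i1 >= i0) keep[i0:min(i1, length(x))] <- FALSE
    }
    x <- x[keep]
  }
  spec <- welch_psd(x - mean(x), env$fs, window_s)
  spec <- dplyr::filter(spec, .data$frequency <= f_max)
  df <- spec$frequency[2] - spec$frequency[1]
  tot <- sum(spec$power) * df
  if (tot > 0) spec$power <- spec$power / tot
  spec
}
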