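# Segmentation of the envelope time axis into pauses, onsets (the first
# 150 ms of speech after each pause) and non-onsets. Detection runs on the
# broadband envelope at the analysis rate, where "near zero" is meaningful;
# the resulting mask is then applied to the band-limited features.

#' Detect pauses and label onset / non-onset samples
#'
#' Samples whose broadband amplitude stays at or below
#' `threshold_frac * (95th percentile of the envelope)` for at least
#' `min_pause_ms` consecutive milliseconds are labelled `pause`. After each
#' pause run, the first `onset_window_ms` of speech (measured from the first
#' supra-threshold sample, shorter if the speech run is shorter) is labelled
#' `onset`; all remaining speech is `non_onset`. Raising `threshold_frac`
#' never shrinks the pause set.
#'
#' @param env broadband [envelope_series()] at the analysis rate.
#' @param threshold_frac fraction of the 95th-percentile amplitude, in (0, 1).
#' @param min_pause_ms minimum pause duration, milliseconds.
#' @param onset_window_ms onset window after each pause, milliseconds.
#' @return a [segment_mask()].
#' @export
detect_pauses <- function(env, threshold_frac = 0.01, min_pause_ms = 100,
                          onset_window_ms = 150) {
  stopifnot(inherits(env, "envelope_series"))
  if (env$band != "broadband") stop("pause detection requires the broadband envelope")
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("`threshold_frac` must be in (0, 1)")
  }
  x <- env$values
  thr <- threshold_frac * stats::quantile(x, 0.95, names = FALSE)
  below <- x <= thr
  min_run <- max(round(min_pause_ms / 1000 * env$fs), 1L)

  labels <- rep("non_onset", length(x))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_pause_run <- r$values & r$lengths >= min_run
  for (k in which(is_pause_run)) labels[starts[k]:ends[k]] <- "pause"
  labels <- label_onsets(labels, env$fs, onset_window_ms)
  segment_mask(labels, env$fs, onset_window_ms = onset_window_ms,
               threshold = thr, min_pause_ms = min_pause_ms)
}

# mark the first onset_window_ms of each speech run that follows a pause run
label_onsets <- function(labels, fs, onset_window_ms) {
  wlen <- round(onset_window_ms / 1000 * fs)
  n <- length(labels)
  is_pause <- labels == "pause"
  r <- rle(is_pause)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next            # not a pause run
    s0 <- ends[k] + 1L                # first speech sample after the pause
    if (s0 > n) next
    s1 <- min(s0 + wlen - 1L, n)
    # clip at the next pause
    run_end <- s1
    nxt <- which(is_pause[s0:s1])
    if (length(nxt)) run_end <- s0 + nxt[1] - 2L
    if (run_end >= s0) labels[s0:run_end] <- "onset"
  }
  labels
}

#' Build a segment mask from generator ground truth
#'
#' Uses the generator's pause intervals directly instead of threshold
#' detection (exact by construction); onset labelling follows the same rule
#' as [detect_pauses()].
#'
#' @param pause_intervals tibble with `start_s`, `end_s`.
#' @param n_samples total length of the axis, samples.
#' @param fs analysis rate, Hz.
#' @param onset_window_ms onset window, milliseconds.
#' @return a [segment_mask()].
#' @export
mask_from_ground_truth <- function(pause_intervals, n_samples, fs,
                                   onset_window_ms = 150) {
  labels <- rep("non_onset", n_samples)
  for (k in seq_len(nrow(pause_intervals))) {
    i0 <- round(pause_intervals$start_s[k] * fs) + 1L
    i1 <- round(pause_intervals$end_s[k] * fs)
    if (i1 >= i0 && i0 <= n_samples) {
      labels[i0:min(i1, n_samples)] <- "pause"
    }
  }
  labels <- label_onsets(labels, fs, onset_window_ms)
  segment_mask(labels, fs, onset_window_ms = onset_window_ms)
}

#' Build a masked speech feature
#'
#' Applies the segmentation to a band-limited envelope, marking which
#' samples are valid for decoder fitting and scoring: `full` keeps all
#' samples; `onsets` keeps only onset-labelled samples; `non_onsets` keeps
#' only non-onset samples; `pauses_removed` keeps all speech samples
#' (onset and non-onset). Excluded samples are retained in the series but
#' flagged invalid, mirroring NaN-style exclusion.
#'
#' @param env band-limited [envelope_series()].
#' @param mask a [segment_mask()] of the same length.
#' @param feature `"full"`, `"onsets"`, `"non_onsets"` or `"pauses_removed"`.
#' @return an [envelope_series()] with its validity mask set.
#' @export
build_feature <- function(env, mask,
                          feature = c("full", "onsets", "non_onsets",
                                      "pauses_removed")) {
  feature <- match.arg(feature)
  stopifnot(inherits(env, "envelope_series"), inherits(mask, "segment_mask"))
  if (length(env$values) != length(mask$labels)) {
    stop("mask and envelope lengths differ (", length(mask$labels), " vs ",
         length(env$values), ")")
  }
  valid <- switch(feature,
    full = rep(TRUE, length(env$values)),
    onsets = mask$labels == "onset",
    non_onsets = mask$labels == "non_onset",
    pauses_removed = mask$labels != "pause"
  )
  envelope_series(env$values, env$fs, band = env$band, mask = valid,
                  provenance = feature)
}

#' Drop pause samples from an envelope and its EEG
#'
#' Removes pause-labelled sample indices from both series, returning
#' index-aligned concatenations of the speech-region samples. (Inside the
#' decoder the same exclusion is applied to the lagged design rows; this
#' function is the raw-series counterpart used e.g. for spectra.)
#'
#' @param env [envelope_series()] at the analysis rate.
#' @param eeg matching [eeg_recording()] (same rate and length).
#' @param mask a [segment_mask()].
#' @return list with trimmed `envelope` and `eeg`.
#' @export
remove_pause_samples <- function(env, eeg, mask) {
  stopifnot(inherits(env, "envelope_series"), inherits(eeg, "eeg_recording"),
            inherits(mask, "segment_mask"))
  n <- length(env$values)
  if (ncol(eeg$data) != n || length(mask$labels) != n) {
    stop("misaligned lengths between envelope, EEG and mask")
  }
  keep <- mask$labels != "pause"
  env$values <- env$values[keep]
  if (!is.null(env$mask)) env$mask <- env$mask[keep]
  env$provenance <- "pauses_removed"
  eeg$data <- eeg$data[, keep, drop = FALSE]
  list(envelope = env, eeg = eeg)
}

#' Amplitude histogram of onset and non-onset samples
#'
#' Binned counts of band-limited envelope amplitudes, separately for onset
#' and non-onset labels, over a common set of breaks. An absent label class
#' yields zero counts and is flagged with a warning.
#'
#' @param env band-limited [envelope_series()].
#' @param mask matching [segment_mask()].
#' @param bins number of bins.
#' @return tibble with columns `label`, `bin_mid`, `count`, plus attributes
#'   `n_onset`, `n_non_onset`, `flagged`.
#' @export
amplitude_histogram <- function(env, mask, bins = 30) {
  stopifnot(inherits(env, "envelope_series"), inherits(mask, "segment_mask"))
  if (length(env$values) != length(mask$labels)) stop("length mismatch")
  on_v <- env$values[mask$labels == "onset"]
  non_v <- env$values[mask$labels == "non_onset"]
  flagged <- length(on_v) == 0 || length(non_v) == 0
  if (flagged) warning("empty label class in amplitude histogram")
  rng <- range(c(on_v, non_v))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  count_in <- function(v) {
    if (!length(v)) return(rep(0L, bins))
    as.integer(table(cut(v, breaks, include.lowest = TRUE)))
  }
  out <- tibble::tibble(
    label = rep(c("onset", "non_onset"), each = bins),
    bin_mid = rep(mids, 2),
    count = c(count_in(on_v), count_in(non_v))
  )
  attr(out, "n_onset") <- length(on_v)
  attr(out, "n_non_onset") <- length(non_v)
  attr(out, "flagged") <- flagged
  out
}
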