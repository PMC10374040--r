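# Core containers. Signals are matrix/vector-backed S3 objects; everything
# derived from them (scores, comparison tables, spectra) is a tibble.

#' Envelope series
#'
#' A speech amplitude envelope at a known sampling rate. Broadband envelopes
#' (straight out of the Hilbert transform) are nonnegative; band-passed
#' envelopes (delta 1-4 Hz, theta 4-8 Hz) oscillate about zero. The optional
#' validity mask implements the NaN-exclusion semantics of the analysis:
#' samples with `mask == FALSE` are excluded from decoder fitting and scoring.
#'
#' @param values numeric vector of envelope samples.
#' @param fs sampling rate in Hz.
#' @param band one of `"broadband"`, `"delta"`, `"theta"`.
#' @param mask optional logical vector (`TRUE` = valid), same length as
#'   `values`. `NULL` means all samples valid.
#' @param provenance one of `"full"`, `"onsets"`, `"non_onsets"`,
#'   `"pauses_removed"`; records which speech feature this series represents.
#' @return an object of class `envelope_series`.
#' @export
envelope_series <- function(values, fs, band = c("broadband", "delta", "theta"),
                            mask = NULL, provenance = "full") {
  band <- match.arg(band)
  values <- as.numeric(values)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive number")
  if (band == "broadband" && length(values) && min(values) < -1e-9) {
    stop("broadband envelope values must be nonnegative")
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(values)) {
      stop("`mask` must have the same length as `values`")
    }
  }
  structure(
    list(values = values, fs = fs, band = band, mask = mask,
         provenance = provenance),
    class = "envelope_series"
  )
}

#' @export
print.envelope_series <- function(x, ...) {
  n_excl <- if (is.null(x$mask)) 0L else sum(!x$mask)
  cat(sprintf(
    "<envelope_series> %s band, %d samples @ %g Hz (%.2f s), %d excluded, feature '%s'\n",
    x$band, length(x$values), x$fs, length(x$values) / x$fs, n_excl,
    x$provenance
  ))
  invisible(x)
}

#' @export
length.envelope_series <- function(x) length(x$values)

# logical validity vector (all TRUE when no mask)
valid_samples <- function(env) {
  if (is.null(env$mask)) rep(TRUE, length(env$values)) else env$mask
}

#' Annotated audio
#'
#' A waveform with word-boundary annotations. Boundaries are a tibble with
#' `onset_s` / `offset_s` (seconds, sorted, non-overlapping) and optionally a
#' `token` column; contractions are treated as a single word when annotations
#' are parsed from TSV.
#'
#' @param samples numeric waveform (nominally in -1..1).
#' @param fs sampling rate in Hz.
#' @param word_boundaries data frame with columns `onset_s`, `offset_s`, and
#'   optionally `token`.
#' @param condition condition label: `"natural"`, `"short"`, `"long"` or
#'   `"other"`.
#' @return object of class `annotated_audio`.
#' @export
annotated_audio <- function(samples, fs, word_boundaries,
                            condition = c("natural", "short", "long", "other")) {
  condition <- match.arg(condition)
  samples <- as.numeric(samples)
  if (fs <= 0) stop("`fs` must be positive")
  wb <- tibble::as_tibble(word_boundaries)
  if (!all(c("onset_s", "offset_s") %in% names(wb))) {
    stop("word boundaries need `onset_s` and `offset_s` columns")
  }
  if (nrow(wb)) {
    if (any(wb$offset_s < wb$onset_s)) stop("word offsets before onsets")
    if (is.unsorted(wb$onset_s)) stop("word boundaries must be sorted")
    if (nrow(wb) > 1 && any(wb$onset_s[-1] < wb$offset_s[-nrow(wb)] - 1e-9)) {
      stop("overlapping word boundaries")
    }
    dur <- length(samples) / fs
    if (any(wb$onset_s < -1e-9) || any(wb$offset_s > dur + 1e-9)) {
      stop("word boundaries outside the recording")
    }
  }
  structure(
    list(samples = samples, fs = fs, word_boundaries = wb,
         condition = condition),
    class = "annotated_audio"
  )
}

#' @export
print.annotated_audio <- function(x, ...) {
  cat(sprintf("<annotated_audio> %.2f s @ %g Hz, %d words, condition '%s'\n",
              length(x$samples) / x$fs, x$fs, nrow(x$word_boundaries),
              x$condition))
  invisible(x)
}

#' EEG recording
#'
#' Multichannel EEG as a channels x samples matrix with identifying metadata.
#'
#' @param data numeric matrix, channels in rows.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row; defaults to
#'   `"Ch1"..."ChN"`.
#' @param subject_id,segment_id,condition identifiers carried through the
#'   pipeline.
#' @param band frequency-band label of the data.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          subject_id = NA_character_, segment_id = NA_integer_,
                          condition = NA_character_,
                          band = c("broadband", "delta", "theta")) {
  band <- match.arg(band)
  data <- as.matrix(data)
  if (anyNA(data)) stop("EEG data must not contain NA")
  if (fs <= 0) stop("`fs` must be positive")
  if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data)) {
    stop("one channel name per data row required")
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = subject_id, segment_id = segment_id,
         condition = condition, band = band),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d ch x %d samples @ %g Hz (%.2f s), band '%s', subject %s seg %s cond %s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$band,
    x$subject_id, x$segment_id, x$condition
  ))
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "eeg_recording")) ncol(x$data) else length(x$values)
}

#' Segment mask
#'
#' Per-sample labels partitioning the envelope time axis into `pause`,
#' `onset` (the first `onset_window_ms` of speech following each pause) and
#' `non_onset` samples, at the analysis rate.
#'
#' @param labels character/factor vector with values in
#'   `c("pause", "onset", "non_onset")`.
#' @param fs sampling rate in Hz.
#' @param onset_window_ms onset window used, milliseconds.
#' @param threshold absolute amplitude threshold used for pause detection
#'   (`NA` for ground-truth masks).
#' @param min_pause_ms minimum pause duration used, milliseconds.
#' @return object of class `segment_mask`.
#' @export
segment_mask <- function(labels, fs, onset_window_ms = 150,
                         threshold = NA_real_, min_pause_ms = NA_real_) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("pause", "onset", "non_onset"))
  if (length(bad)) stop("unknown mask labels: ", paste(bad, collapse = ", "))
  structure(
    list(labels = labels, fs = fs, onset_window_ms = onset_window_ms,
         threshold = threshold, min_pause_ms = min_pause_ms),
    class = "segment_mask"
  )
}

#' @export
print.segment_mask <- function(x, ...) {
  tab <- table(factor(x$labels, c("pause", "onset", "non_onset")))
  cat(sprintf(
    "<segment_mask> %d samples @ %g Hz: %d pause, %d onset, %d non_onset\n",
    length(x$labels), x$fs, tab[["pause"]], tab[["onset"]], tab[["non_onset"]]
  ))
  invisible(x)
}

#' @export
length.segment_mask <- function(x) length(x$labels)
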