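# EEG preprocessing: common-average reference, zero-phase FIR band-pass,
# resampling to the analysis rate, per-channel z-normalisation.

#' Re-reference EEG to the common average
#'
#' Subtracts the instantaneous cross-channel mean from every channel; the
#' cross-channel mean of the output is zero at every sample. Idempotent.
#'
#' @param eeg an [eeg_recording()].
#' @export
rereference_common_average <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (nrow(eeg$data) < 2) stop("common-average reference needs >= 2 channels")
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

#' Band-pass filter EEG with a zero-phase FIR filter
#'
#' Linear-phase FIR filter (Hamming window design) applied with group-delay
#' compensation, so the net phase is zero. The filter length follows the
#' rule `round(6.6 * fs / shortest transition bandwidth)` (forced odd);
#' transition bandwidths are 25% of each corner frequency, with the upper
#' transition floored at 2 Hz and the lower transition capped at the lower
#' corner. Delta = 1-4 Hz, theta = 4-8 Hz. Identical filter contract to
#' [bandlimit_envelope()].
#'
#' @param eeg a broadband [eeg_recording()].
#' @param band `"delta"` or `"theta"`.
#' @export
bandpass_eeg <- function(eeg, band = c("delta", "theta")) {
  band <- match.arg(band)
  stopifnot(inherits(eeg, "eeg_recording"))
  if (eeg$band != "broadband") stop("input EEG must be broadband")
  edges <- band_edges(band)
  taps <- design_fir_bandpass(eeg$fs, edges[1], edges[2])
  if (ncol(eeg$data) < length(taps)) {
    stop("recording shorter than the filter (", length(taps), " taps)")
  }
  eeg$data <- filter_matrix_zerophase(eeg$data, taps)
  eeg$band <- band
  eeg
}

#' Resample EEG to the analysis rate
#'
#' @param eeg an [eeg_recording()], band-limited below `fs_out / 2`.
#' @param fs_out output rate, Hz (default 128).
#' @export
resample_eeg <- function(eeg, fs_out = 128) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (fs_out <= 0) stop("`fs_out` must be positive")
  if (eeg$fs == fs_out) return(eeg)
  eeg$data <- t(apply(eeg$data, 1L, resample_signal,
                      fs_in = eeg$fs, fs_out = fs_out))
  eeg$fs <- fs_out
  eeg
}

#' Z-normalise EEG channels
#'
#' Each channel is scaled to mean 0 and standard deviation 1 over the whole
#' recording (population 1/N convention).
#'
#' @param eeg an [eeg_recording()].
#' @export
normalize_eeg <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_recording"))
  n <- ncol(eeg$data)
  mu <- rowMeans(eeg$data)
  centred <- eeg$data - mu
  sdev <- sqrt(rowMeans(centred^2))
  if (any(sdev == 0)) {
    stop("zero-variance channel(s): ",
         paste(eeg$channel_names[sdev == 0], collapse = ", "))
  }
  eeg$data <- centred / sdev
  eeg
}

#' Full EEG preprocessing chain
#'
#' Common-average reference, zero-phase band-pass into `band`, resample to
#' `fs_out`, z-normalise — in that order. Deterministic.
#'
#' @inheritParams bandpass_eeg
#' @param fs_out analysis rate, Hz.
#' @export
preprocess_eeg <- function(eeg, band = c("delta", "theta"), fs_out = 128) {
  band <- match.arg(band)
  eeg |>
    rereference_common_average() |>
    bandpass_eeg(band) |>
    resample_eeg(fs_out) |>
    normalize_eeg()
}
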