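# Internal signal-processing primitives shared by the stimulus and EEG paths.
# All band-pass filtering in the package goes through design_fir_bandpass() /
# apply_fir_zerophase() so the envelope and the EEG see the same filter
# contract.

#' Design a linear-phase FIR band-pass filter
#'
#' Window-design (Hamming) band-pass filter whose length follows the
#' "6.6 cycles of the shortest transition band" rule:
#' `L = round(6.6 * fs / min(transition bandwidths))`, forced odd so the
#' filter is type-I and has an integer group delay.
#'
#' Transition bandwidths default to 25% of each corner frequency, with the
#' upper transition floored at 2 Hz and the lower transition capped at the
#' lower corner itself (so the stopband never crosses 0 Hz). Half the
#' transition band is placed on either side of each corner.
#'
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi passband corner frequencies in Hz.
#' @param trans_lo,trans_hi optional explicit transition bandwidths in Hz.
#' @return numeric vector of filter taps (odd length).
#' @keywords internal
design_fir_bandpass <- function(fs, f_lo, f_hi, trans_lo = NULL, trans_hi = NULL) {
  stopifnot(fs > 0, f_lo > 0, f_hi > f_lo, f_hi < fs / 2)
  if (is.null(trans_lo)) trans_lo <- min(max(0.25 * f_lo, 2), f_lo)
  if (is.null(trans_hi)) trans_hi <- min(max(0.25 * f_hi, 2), fs / 2 - f_hi)
  shortest <- min(trans_lo, trans_hi)
  len <- round(6.6 * fs / shortest)
  if (len %% 2 == 0) len <- len + 1
  # cutoffs at the midpoint of each transition band
  w <- c(f_lo - trans_lo / 2, f_hi + trans_hi / 2) / (fs / 2)
  taps <- signal::fir1(len - 1, w, type = "pass")
  as.numeric(taps)
}

#' Apply an odd-length linear-phase FIR filter with zero net phase
#'
#' Convolves the signal with the taps (FFT-based) and removes the
#' `(L-1)/2`-sample group delay, so a symmetric filter leaves features at
#' their original latency. Edges are implicitly zero-padded.
#'
#' @param x numeric signal.
#' @param taps odd-length FIR taps.
#' @keywords internal
apply_fir_zerophase <- function(x, taps) {
  len <- length(taps)
  stopifnot(len %% 2 == 1)
  if (length(x) < 1L) stop("empty signal")
  gd <- (len - 1L) / 2L
  n <- length(x)
  y <- fft_conv(x, taps)
  y[(gd + 1L):(gd + n)]
}

# full linear convolution via zero-padded FFT (padded to a highly
# composite length so the transform stays O(n log n))
fft_conv <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  N <- stats::nextn(n_out, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(N - length(x))))
  H <- stats::fft(c(h, numeric(N - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n_out)] / N
}

# Zero-phase band-pass across the rows of a channels x samples matrix.
filter_matrix_zerophase <- function(mat, taps) {
  t(apply(mat, 1L, apply_fir_zerophase, taps = taps))
}

#' Resample a signal between two rates
#'
#' Fourier resampling (spectrum truncation / zero-padding), which is exact
#' for band-limited signals and introduces no group delay — every signal
#' resampled in this package has already been low-passed well below both
#' Nyquist rates. Duration is preserved within one output sample.
#'
#' @param x numeric signal.
#' @param fs_in,fs_out sampling rates in Hz.
#' @return numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @keywords internal
resample_signal <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(x)
  n_out <- round(length(x) * fs_out / fs_in)
  q <- fs_in / fs_out
  if (abs(q - round(q)) < 1e-9) {
    # integer decimation: every signal resampled here is already band
    # limited far below the output Nyquist rate, so plain sample picking
    # is alias-free, exact in amplitude and free of edge ringing
    q <- round(q)
    idx <- 1L + (seq_len(n_out) - 1L) * q
    return(x[idx])
  }
  resample_fft(x, n_out)
}

# Fourier-domain resampling (spectrum truncation / zero-padding). Amplitude
# is preserved; the output has n_out samples spanning the same duration.
resample_fft <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  half <- floor(min(n, n_out) / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Analytic signal via the frequency domain
#'
#' Standard construction: zero the negative frequencies, double the positive
#' ones, inverse-transform. `Mod(analytic_signal(x))` is the amplitude
#' envelope of `x`.
#'
#' @param x real signal.
#' @return complex vector, same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Gaussian 1/f^a noise
#'
#' Spectrally shaped Gaussian noise generated in the frequency domain:
#' white Gaussian noise whose spectrum is scaled by `f^(-exponent/2)` (power
#' proportional to `1/f^exponent`), DC removed. Uses the current RNG state.
#'
#' @param n number of samples.
#' @param exponent spectral slope (1 = pink).
#' @keywords internal
pink_noise <- function(n, exponent = 1) {
  if (exponent == 0) return(stats::rnorm(n))
  # shape on a composite-length grid (fast FFT), keep the first n samples
  N <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(N)
  X <- stats::fft(w)
  f <- c(0, seq_len(N - 1))
  f <- pmin(f, N - f)        # symmetric frequency index
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE))[seq_len(n)] / N
  y / stats::sd(y)
}

#' Averaged-periodogram (Welch) power spectral density
#'
#' Hamming-windowed segments with 50% overlap; one-sided PSD.
#'
#' @param x signal.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds.
#' @return tibble with columns `frequency` (Hz) and `power`.
#' @keywords internal
welch_psd <- function(x, fs, window_s = 4) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("signal shorter than one analysis window")
  step <- floor(nwin / 2)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- signal::hamming(nwin)
  acc <- numeric(floor(nwin / 2) + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)] * w
    X <- stats::fft(seg)
    p <- Mod(X[seq_along(acc)])^2
    acc <- acc + p
  }
  acc <- acc / length(starts)
  freq <- (seq_along(acc) - 1) * fs / nwin
  tibble::tibble(frequency = freq, power = acc)
}
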