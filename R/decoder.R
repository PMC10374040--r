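# Backward mTRF (decoder): reconstructs the speech envelope from lagged
# multichannel EEG,
#
#   S_hat(t) = sum_n sum_tau r(t + tau, n) g(tau, n),
#
# with weights estimated by Tikhonov-regularised least squares,
#
#   g = (R'R + lambda M)^-1 R'S,
#
# where M is a per-channel second-difference (smoothness) penalty across
# lags. Columns of the design and the target are mean-centred over the
# retained rows before solving; no intercept column is added (the constant
# vector lies in each block's penalty null space, so an unpenalised
# intercept would be redundant and ill-conditioned). Pearson's r is
# offset-invariant, so centring does not affect scoring.

#' Lag specification
#'
#' The decoder's lag window. The anticausal convention is used: EEG at
#' `t + tau` predicts the stimulus at `t`, for `tau` on a sample grid from
#' `lag_min_ms` to `lag_max_ms`.
#'
#' @param lag_min_ms,lag_max_ms lag window in milliseconds (defaults 0-300;
#'   the longer-lag variant uses 0-500).
#' @param fs sampling rate in Hz.
#' @return object of class `lag_spec` with the integer sample lags and
#'   `n_lags = round((lag_max - lag_min)/1000 * fs) + 1`.
#' @export
lag_spec <- function(lag_min_ms = 0, lag_max_ms = 300, fs = 128) {
  if (lag_min_ms > lag_max_ms) stop("`lag_min_ms` must be <= `lag_max_ms`")
  l0 <- round(lag_min_ms / 1000 * fs)
  l1 <- round(lag_max_ms / 1000 * fs)
  structure(
    list(lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms, fs = fs,
         lags = l0:l1, n_lags = l1 - l0 + 1L),
    class = "lag_spec"
  )
}

#' Build the lagged EEG design matrix
#'
#' Row `t` contains `r(t + tau, n)` for every lag `tau` and channel `n`.
#' Samples beyond the recording (`t + tau > N` or `< 1`) are zero-padded.
#' Column order is channel-major: all lags of channel 1, then all lags of
#' channel 2, etc. — matching the block structure of [build_regularizer()].
#'
#' @param eeg an [eeg_recording()] at the analysis rate (normalised), or a
#'   channels x samples matrix.
#' @param spec a [lag_spec()].
#' @return numeric matrix, `n_samples` x `(n_lags * n_channels)`.
#' @export
build_lagged_design <- function(eeg, spec) {
  mat <- if (inherits(eeg, "eeg_recording")) eeg$data else as.matrix(eeg)
  n <- ncol(mat)
  if (spec$n_lags > n) stop("lag window longer than the recording")
  nch <- nrow(mat)
  out <- matrix(0, n, spec$n_lags * nch)
  t_idx <- seq_len(n)
  for (ch in seq_len(nch)) {
    x <- mat[ch, ]
    for (j in seq_along(spec$lags)) {
      src <- t_idx + spec$lags[j]
      ok <- src >= 1L & src <= n
      col <- numeric(n)
      col[ok] <- x[src[ok]]
      out[, (ch - 1L) * spec$n_lags + j] <- col
    }
  }
  out
}

#' Build the second-difference regularisation matrix
#'
#' Block-diagonal matrix with one `n_lags` x `n_lags` tridiagonal block per
#' channel: diagonal `(1, 2, ..., 2, 1)`, off-diagonals `-1`. Each block is
#' symmetric positive semidefinite, annihilates the constant vector (row
#' sums are zero) and penalises curvature of the weights across lags; there
#' is no coupling across channels. With a single lag the block degenerates
#' to the 1x1 identity.
#'
#' @param spec a [lag_spec()].
#' @param n_channels number of EEG channels.
#' @return square matrix of side `n_lags * n_channels`.
#' @export
build_regularizer <- function(spec, n_channels) {
  p <- spec$n_lags
  if (p == 1L) {
    block <- matrix(1, 1, 1)
  } else {
    block <- diag(c(1, rep(2, p - 2), 1))
    for (i in seq_len(p - 1)) {
      block[i, i + 1] <- -1
      block[i + 1, i] <- -1
    }
  }
  blocks <- replicate(n_channels, block, simplify = FALSE)
  out <- matrix(0, p * n_channels, p * n_channels)
  for (ch in seq_len(n_channels)) {
    idx <- ((ch - 1) * p + 1):(ch * p)
    out[idx, idx] <- block
  }
  out
}

#' Fit a decoder by regularised least squares
#'
#' Rows whose target sample is excluded (validity mask `FALSE`, or `NA` in
#' the target) are dropped from both the design and the target; the
#' remaining rows are column-centred (and the target mean-centred) and the
#' penalised normal equations `(R'R + lambda M) g = R'S` are solved by a
#' symmetric positive-definite (Cholesky) factorisation, falling back to a
#' QR least-squares solve if the factorisation fails. An exactly singular
#' system raises an error advising `lambda > 0`.
#'
#' @param design design matrix from [build_lagged_design()].
#' @param target numeric target vector, or an [envelope_series()] whose mask
#'   supplies the exclusions.
#' @param lambda regularisation scalar (>= 0), applied to `M` unscaled.
#' @param M regularisation matrix (default built from `spec`/`n_channels`).
#' @param spec the [lag_spec()] used to build the design.
#' @param n_channels number of EEG channels in the design.
#' @param mask optional logical validity vector overriding the target's.
#' @param band,trained_on,condition metadata stamped on the model.
#' @return object of class `decoder_model`: weights as an
#'   `n_lags` x `n_channels` matrix plus fitting metadata.
#' @export
fit_decoder <- function(design, target, lambda, M = NULL, spec = NULL,
                        n_channels = NULL, mask = NULL,
                        band = NA_character_, trained_on = "full",
                        condition = NA_character_) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (inherits(target, "envelope_series")) {
    if (is.null(mask)) mask <- valid_samples(target)
    y <- target$values
    if (is.na(band)) band <- target$band
  } else {
    y <- as.numeric(target)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  mask <- mask & !is.na(y)
  if (nrow(design) != length(y)) stop("design rows must align with target samples")
  p <- ncol(design)
  if (is.null(n_channels)) {
    n_channels <- if (!is.null(spec)) p / spec$n_lags else 1L
  }
  if (is.null(M)) {
    if (is.null(spec)) stop("provide `M` or `spec`")
    M <- build_regularizer(spec, n_channels)
  }
  if (!all(dim(M) == p)) stop("regulariser dimension mismatch")

  X <- design[mask, , drop = FALSE]
  yv <- y[mask]
  if (nrow(X) < 2) stop("too few valid samples to fit")
  cm <- colMeans(X)
  X <- sweep(X, 2, cm)
  ym <- mean(yv)
  yv <- yv - ym

  A <- crossprod(X) + lambda * M
  b <- crossprod(X, yv)
  g <- solve_spd(A, b, lambda)

  structure(
    list(
      weights = matrix(g, nrow = if (!is.null(spec)) spec$n_lags else p,
                       ncol = n_channels),
      g = as.numeric(g),
      lag_spec = spec,
      lambda = lambda,
      band = band,
      trained_on = trained_on,
      condition = condition,
      col_means = cm,
      target_mean = ym,
      n_fit = nrow(X)
    ),
    class = "decoder_model"
  )
}

# Cholesky factor with an escalating diagonal jitter fallback. The
# penalised system is singular by construction whenever the EEG is
# common-average referenced: the all-ones weight vector lies in the null
# space of both the lagged design (channel columns sum to zero at every
# lag) and the penalty (constant across lags). The right-hand side is
# orthogonal to that null space (b = X'y and X annihilates it), so a tiny
# ridge on the diagonal returns the minimum-norm solution at Cholesky cost.
chol_safe <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  eps <- mean(diag(A)) * 1e-10
  for (i in 1:4) {
    ch <- tryCatch(chol(A + diag(eps, nrow(A))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    eps <- eps * 100
  }
  NULL
}

# Solve the penalised normal equations. A singular unregularised system
# errors with advice; at lambda > 0 the jittered Cholesky (minimum-norm)
# path is used, with an SVD pseudoinverse as the last resort.
solve_spd <- function(A, b, lambda = NULL) {
  ch <- if (is.null(lambda) || lambda > 0) {
    chol_safe(A)
  } else {
    tryCatch(chol(A), error = function(e) NULL)
  }
  if (!is.null(ch)) {
    return(backsolve(ch, backsolve(ch, b, transpose = TRUE)))
  }
  out <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (!is.null(out)) return(out)
  if (!is.null(lambda) && lambda == 0) {
    stop("singular normal equations; use lambda > 0")
  }
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!any(keep)) stop("singular normal equations; use lambda > 0")
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model> %d lags x %d channels, lambda = %g, band '%s', trained on '%s'\n",
    nrow(x$weights), ncol(x$weights), x$lambda, x$band, x$trained_on
  ))
  invisible(x)
}

#' Tidy a decoder model
#'
#' One row per (lag, channel) weight.
#' @param x a `decoder_model`.
#' @param ... unused.
#' @return tibble with `lag_ms`, `channel`, `weight`.
#' @exportS3Method generics::tidy
tidy.decoder_model <- function(x, ...) {
  lags_ms <- if (!is.null(x$lag_spec)) {
    x$lag_spec$lags / x$lag_spec$fs * 1000
  } else {
    seq_len(nrow(x$weights)) - 1
  }
  tidyr::expand_grid(channel = seq_len(ncol(x$weights)), lag_ms = lags_ms) |>
    dplyr::mutate(weight = as.numeric(x$weights)) |>
    dplyr::select("lag_ms", "channel", "weight")
}

#' Glance at a decoder model
#' @param x a `decoder_model`.
#' @param ... unused.
#' @return one-row tibble of fitting metadata.
#' @exportS3Method generics::glance
glance.decoder_model <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    n_lags = nrow(x$weights),
    n_channels = ncol(x$weights),
    n_fit = x$n_fit,
    band = x$band,
    trained_on = x$trained_on,
    condition = x$condition
  )
}

#' Reconstruct the stimulus feature from a design matrix
#'
#' Plain linear map `S_hat = R g`, same length as the design's time axis.
#' (Within cross-validation, predictions additionally carry the training
#' centring offset; Pearson's r is unaffected by it.)
#'
#' @param model a `decoder_model`.
#' @param design design matrix built with the model's lag specification and
#'   channel order.
#' @param center if `TRUE`, apply the training centring offset
#'   (`(R - m) g + ybar`) instead of the raw product.
#' @return numeric vector of reconstructed samples.
#' @export
reconstruct <- function(model, design, center = FALSE) {
  if (ncol(design) != length(model$g)) stop("design/weights shape mismatch")
  if (center) {
    as.numeric(sweep(design, 2, model$col_means) %*% model$g) + model$target_mean
  } else {
    as.numeric(design %*% model$g)
  }
}

#' Score a reconstruction against the target feature
#'
#' Pearson's r and mean squared error over the valid (unmasked) samples
#' only. Fewer than 3 valid samples, or zero variance in either series,
#' yields `NA` values flagged with a warning, never a silent zero.
#'
#' @param s_hat reconstructed series.
#' @param target [envelope_series()] (mask respected) or numeric vector.
#' @param mask optional logical validity vector.
#' @return one-row tibble: `pearson_r`, `mse`, `n_valid`, `flagged`.
#' @export
score_reconstruction <- function(s_hat, target, mask = NULL) {
  if (inherits(target, "envelope_series")) {
    if (is.null(mask)) mask <- valid_samples(target)
    y <- target$values
  } else {
    y <- as.numeric(target)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  mask <- mask & !is.na(y) & !is.na(s_hat)
  if (length(s_hat) != length(y)) stop("series lengths differ")
  a <- s_hat[mask]
  b <- y[mask]
  n <- length(a)
  if (n < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("undefined score: <3 valid samples or zero variance")
    return(tibble::tibble(pearson_r = NA_real_, mse = NA_real_,
                          n_valid = n, flagged = TRUE))
  }
  tibble::tibble(
    pearson_r = stats::cor(a, b),
    mse = mean((a - b)^2),
    n_valid = n,
    flagged = FALSE
  )
}

#' The default regularisation grid
#'
#' 50 logarithmically spaced values from 0.01 to 1e12.
#' @param n_points number of grid points.
#' @param lambda_min,lambda_max grid bounds.
#' @export
default_lambda_grid <- function(n_points = 50, lambda_min = 0.01,
                                lambda_max = 1e12) {
  exp(seq(log(lambda_min), log(lambda_max), length.out = n_points))
}
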