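# Leave-one-out cross-validated envelope reconstruction with lambda-grid
# search, the train x test speech-feature grid, duration matching and
# pauses-removed decoding.
#
# The engine works on per-segment sufficient statistics (X'X, X'y, column
# sums, target sums over the retained rows), which makes fitting across the
# 50-point lambda grid and re-running the whole CV inside each permutation
# cheap. Dropping a row from the statistics is algebraically identical to
# physically deleting it, so NaN-style exclusion and row deletion coincide
# exactly (this equivalence is tested).

#' Cross-validation plan
#'
#' Bundles the segments of one (subject, condition, band) cell with the
#' evaluation settings. Each segment is a list with elements `eeg` (an
#' [eeg_recording()] at the analysis rate, normalised), `envelope` (the
#' band-limited [envelope_series()]) and `mask` (a [segment_mask()]).
#'
#' @param segments list of >= 2 segments (leave-one-out needs at least two).
#' @param lambda_grid strictly increasing regularisation grid.
#' @param spec a [lag_spec()].
#' @param train_feature,test_feature speech feature used for fitting /
#'   scoring: `"full"`, `"onsets"`, `"non_onsets"` or `"pauses_removed"`.
#' @param truncation_s optional truncation applied to every segment, seconds.
#' @param pauses_removed if `TRUE`, decode with pause samples excluded from
#'   design rows and target on both sides of the CV.
#' @param subject,condition,band cell labels carried into results.
#' @return object of class `cv_plan`.
#' @export
cv_plan <- function(segments, lambda_grid = default_lambda_grid(),
                    spec = lag_spec(), train_feature = "full",
                    test_feature = train_feature, truncation_s = NULL,
                    pauses_removed = FALSE, subject = NA, condition = NA,
                    band = NA) {
  if (length(segments) < 2) stop("need >= 2 segments for leave-one-out")
  if (is.unsorted(lambda_grid, strictly = TRUE)) {
    stop("`lambda_grid` must be strictly increasing")
  }
  structure(
    list(segments = segments, lambda_grid = lambda_grid, spec = spec,
         train_feature = train_feature, test_feature = test_feature,
         truncation_s = truncation_s, pauses_removed = pauses_removed,
         subject = subject, condition = condition, band = band),
    class = "cv_plan"
  )
}

# Trim envelope, EEG and mask of one segment to a common sample count.
align_segment <- function(seg) {
  n <- min(length(seg$envelope$values), ncol(seg$eeg$data),
           length(seg$mask$labels))
  seg$envelope$values <- seg$envelope$values[seq_len(n)]
  if (!is.null(seg$envelope$mask)) {
    seg$envelope$mask <- seg$envelope$mask[seq_len(n)]
  }
  seg$eeg$data <- seg$eeg$data[, seq_len(n), drop = FALSE]
  seg$mask$labels <- seg$mask$labels[seq_len(n)]
  seg
}

feature_valid <- function(seg, feature) {
  v <- switch(feature,
    full = rep(TRUE, length(seg$mask$labels)),
    onsets = seg$mask$labels == "onset",
    non_onsets = seg$mask$labels == "non_onset",
    pauses_removed = seg$mask$labels != "pause",
    stop("unknown feature: ", feature)
  )
  if (!is.null(seg$envelope$mask)) v <- v & seg$envelope$mask
  v
}

# Sufficient statistics of one segment restricted to rows `valid`.
suff_stats <- function(X, y, valid) {
  Xv <- X[valid, , drop = FALSE]
  yv <- y[valid]
  list(
    n = nrow(Xv),
    cs = colSums(Xv),
    A = crossprod(Xv),
    b = as.numeric(crossprod(Xv, yv)),
    ys = sum(yv),
    yss = sum(yv^2)
  )
}

add_stats <- function(stats_list) {
  out <- stats_list[[1]]
  for (s in stats_list[-1]) {
    out$n <- out$n + s$n
    out$cs <- out$cs + s$cs
    out$A <- out$A + s$A
    out$b <- out$b + s$b
    out$ys <- out$ys + s$ys
    out$yss <- out$yss + s$yss
  }
  out
}

# Fit weights for each lambda from aggregated (uncentred) training stats.
fit_from_stats <- function(tr, M, lambda_grid) {
  m <- tr$cs / tr$n
  ybar <- tr$ys / tr$n
  A_c <- tr$A - tr$n * tcrossprod(m)
  b_c <- tr$b - tr$n * m * ybar
  lapply(lambda_grid, function(l) solve_spd(A_c + l * M, b_c, l))
}

# Pearson r and MSE of the centred-prediction on a test segment's stats.
score_from_stats <- function(g, te, m_train, ybar_train) {
  if (te$n < 3) return(c(r = NA_real_, mse = NA_real_))
  mk <- te$cs / te$n
  yk <- te$ys / te$n
  pg <- sum(mk * g)
  gAg <- as.numeric(crossprod(g, te$A %*% g))
  cov_term <- sum(g * te$b) - te$n * pg * yk
  varp <- gAg - te$n * pg^2
  vart <- te$yss - te$n * yk^2
  if (varp <= 0 || vart <= 0) return(c(r = NA_real_, mse = NA_real_))
  r <- cov_term / sqrt(varp * vart)
  c0 <- ybar_train - sum(m_train * g)
  sse <- te$yss - 2 * sum(g * te$b) - 2 * c0 * te$ys + gAg +
    2 * c0 * sum(te$cs * g) + te$n * c0^2
  c(r = r, mse = sse / te$n)
}

# lambda-selection rule: highest mean r, ties (within 1e-12) to the smaller
# lambda. Grid is increasing, so the first qualifying index wins.
select_lambda_index <- function(mean_r) {
  best <- max(mean_r, na.rm = TRUE)
  which(mean_r >= best - 1e-12)[1]
}

# Per-segment sufficient statistics for a set of features, computed once
# per segment (design construction and Gram products are the expensive
# part and are shared across feature cells).
prepare_stats <- function(segments, spec, features, truncation_s = NULL) {
  segs <- lapply(segments, align_segment)
  if (!is.null(truncation_s)) {
    segs <- lapply(segs, truncate_segment, seconds = truncation_s)
  }
  nch <- nrow(segs[[1]]$eeg$data)
  st <- lapply(features, function(f) vector("list", length(segs)))
  names(st) <- features
  for (i in seq_along(segs)) {
    X <- build_lagged_design(segs[[i]]$eeg, spec)
    y <- segs[[i]]$envelope$values
    for (f in features) {
      st[[f]][[i]] <- suff_stats(X, y, feature_valid(segs[[i]], f))
    }
  }
  list(stats = st, n_channels = nch, n_segments = length(segs))
}

# Core CV over precomputed stats. st_train / st_test: lists of per-segment
# stats. Returns the fold r/mse matrices (segments x lambdas).
cv_from_stats <- function(st_train, st_test, M, lambda_grid) {
  n_seg <- length(st_train)
  n_lam <- length(lambda_grid)
  fold_r <- matrix(NA_real_, n_seg, n_lam)
  fold_mse <- matrix(NA_real_, n_seg, n_lam)
  for (k in seq_len(n_seg)) {
    tr <- add_stats(st_train[-k])
    gs <- fit_from_stats(tr, M, lambda_grid)
    m_train <- tr$cs / tr$n
    ybar_train <- tr$ys / tr$n
    for (j in seq_len(n_lam)) {
      sc <- score_from_stats(gs[[j]], st_test[[k]], m_train, ybar_train)
      fold_r[k, j] <- sc[["r"]]
      fold_mse[k, j] <- sc[["mse"]]
    }
  }
  list(r = fold_r, mse = fold_mse)
}

# Assemble an eval_result from fold matrices after lambda selection.
make_eval_result <- function(folds, lambda_grid, labels) {
  n_flagged <- sum(apply(folds$r, 1, function(z) all(is.na(z))))
  if (n_flagged > 0) {
    warning(n_flagged, " fold(s) with undefined scores excluded from the mean")
  }
  mean_r <- colMeans(folds$r, na.rm = TRUE)
  mean_mse <- colMeans(folds$mse, na.rm = TRUE)
  sel <- select_lambda_index(mean_r)
  structure(
    c(
      list(
        fold = tibble::tibble(
          fold = seq_len(nrow(folds$r)),
          pearson_r = folds$r[, sel],
          mse = folds$mse[, sel]
        ),
        by_lambda = tibble::tibble(
          lambda = lambda_grid, mean_r = mean_r, mean_mse = mean_mse
        ),
        selected_lambda = lambda_grid[sel],
        mean_r = mean_r[sel],
        mean_mse = mean_mse[sel],
        n_flagged_folds = n_flagged
      ),
      labels
    ),
    class = "eval_result"
  )
}

#' Run leave-one-out cross-validation for one cell
#'
#' For every fold, the decoder is fitted on the concatenated training
#' segments (train-feature exclusions applied; segments are concatenated
#' after design construction, so no lagged row spans a segment boundary)
#' and scored on the held-out segment (test-feature exclusions applied).
#' Fold correlations are averaged per lambda and the lambda maximising the
#' mean Pearson r is selected (ties to the smaller lambda). Folds with an
#' undefined score are excluded from the mean and counted.
#'
#' @param plan a [cv_plan()].
#' @return object of class `eval_result`: per-fold and mean r / MSE at the
#'   selected lambda, the full lambda profile, and the cell labels.
#' @export
run_cv <- function(plan) {
  stopifnot(inherits(plan, "cv_plan"))
  train_feature <- plan$train_feature
  test_feature <- plan$test_feature
  if (plan$pauses_removed) {
    train_feature <- test_feature <- "pauses_removed"
  }
  prep <- prepare_stats(plan$segments, plan$spec,
                        unique(c(train_feature, test_feature)),
                        plan$truncation_s)
  M <- build_regularizer(plan$spec, prep$n_channels)
  folds <- cv_from_stats(prep$stats[[train_feature]],
                         prep$stats[[test_feature]], M, plan$lambda_grid)
  make_eval_result(folds, plan$lambda_grid, list(
    subject = plan$subject, condition = plan$condition, band = plan$band,
    train_feature = train_feature, test_feature = test_feature,
    truncation_s = plan$truncation_s,
    pauses_removed = plan$pauses_removed,
    lag_window = c(plan$spec$lag_min_ms, plan$spec$lag_max_ms)
  ))
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> subject %s, %s/%s band %s: train %s -> test %s\n  mean r = %.4f, mse = %.4g, lambda = %.3g (%d folds%s)\n",
    x$subject, x$condition, if (x$pauses_removed) "pauses-removed" else "full-axis",
    x$band, x$train_feature, x$test_feature, x$mean_r, x$mean_mse,
    x$selected_lambda, nrow(x$fold),
    if (x$n_flagged_folds) paste0(", ", x$n_flagged_folds, " flagged") else ""
  ))
  invisible(x)
}

#' @rdname run_cv
#' @param x an `eval_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.eval_result <- function(x, ...) {
  dplyr::mutate(
    x$fold,
    subject = x$subject, condition = x$condition, band = x$band,
    train_feature = x$train_feature, test_feature = x$test_feature,
    selected_lambda = x$selected_lambda
  )
}

#' @rdname run_cv
#' @exportS3Method generics::glance
glance.eval_result <- function(x, ...) {
  tibble::tibble(
    subject = x$subject, condition = x$condition, band = x$band,
    train_feature = x$train_feature, test_feature = x$test_feature,
    mean_r = x$mean_r, mean_mse = x$mean_mse,
    selected_lambda = x$selected_lambda,
    n_folds = nrow(x$fold), n_flagged_folds = x$n_flagged_folds,
    truncation_s = x$truncation_s %||% NA_real_,
    pauses_removed = x$pauses_removed,
    lag_max_ms = x$lag_window[2]
  )
}

#' Evaluate the full train x test speech-feature grid
#'
#' All nine (train, test) cells over `{full, onsets, non_onsets}` with
#' shared folds; each cell selects its own lambda. Decoder fits are shared
#' across cells with the same training feature.
#'
#' @param segments as in [cv_plan()].
#' @param features feature set tested on.
#' @param train_features features trained on (defaults to `features`,
#'   giving the full nine-cell grid; restricting to `"full"` gives the
#'   three cells highlighted in the headline comparisons).
#' @inheritParams cv_plan
#' @return tibble with one row per cell (from [glance.eval_result()]) and a
#'   list-column `result` holding the full `eval_result`s.
#' @export
feature_grid <- function(segments, lambda_grid = default_lambda_grid(),
                         spec = lag_spec(),
                         features = c("full", "onsets", "non_onsets"),
                         train_features = features,
                         truncation_s = NULL, subject = NA, condition = NA,
                         band = NA) {
  prep <- prepare_stats(segments, spec, unique(c(features, train_features)),
                        truncation_s)
  M <- build_regularizer(spec, prep$n_channels)
  n_seg <- prep$n_segments
  n_lam <- length(lambda_grid)

  res <- list()
  for (tf in train_features) {
    # one set of decoder fits per training feature, scored on every
    # test feature (shared folds; each cell still selects its own lambda)
    fold_r <- lapply(features, function(f) matrix(NA_real_, n_seg, n_lam))
    fold_mse <- lapply(features, function(f) matrix(NA_real_, n_seg, n_lam))
    names(fold_r) <- names(fold_mse) <- features
    for (k in seq_len(n_seg)) {
      tr <- add_stats(prep$stats[[tf]][-k])
      gs <- fit_from_stats(tr, M, lambda_grid)
      m_train <- tr$cs / tr$n
      ybar_train <- tr$ys / tr$n
      for (sf in features) {
        te <- prep$stats[[sf]][[k]]
        for (j in seq_len(n_lam)) {
          sc <- score_from_stats(gs[[j]], te, m_train, ybar_train)
          fold_r[[sf]][k, j] <- sc[["r"]]
          fold_mse[[sf]][k, j] <- sc[["mse"]]
        }
      }
    }
    for (sf in features) {
      res[[paste(tf, sf, sep = "->")]] <- make_eval_result(
        list(r = fold_r[[sf]], mse = fold_mse[[sf]]), lambda_grid,
        list(subject = subject, condition = condition, band = band,
             train_feature = tf, test_feature = sf,
             truncation_s = truncation_s, pauses_removed = FALSE,
             lag_window = c(spec$lag_min_ms, spec$lag_max_ms))
      )
    }
  }
  dplyr::bind_rows(lapply(res, glance)) |>
    dplyr::mutate(result = unname(res))
}

truncate_segment <- function(seg, seconds) {
  n_keep <- round(seconds * seg$envelope$fs)
  n <- length(seg$envelope$values)
  if (n < n_keep) {
    stop("segment shorter than the requested truncation (",
         round(n / seg$envelope$fs, 1), " s < ", seconds, " s)")
  }
  idx <- seq_len(n_keep)
  seg$envelope$values <- seg$envelope$values[idx]
  if (!is.null(seg$envelope$mask)) seg$envelope$mask <- seg$envelope$mask[idx]
  seg$eeg$data <- seg$eeg$data[, idx, drop = FALSE]
  seg$mask$labels <- seg$mask$labels[idx]
  seg
}

#' Truncate a plan's segments for duration matching
#'
#' Keeps the first `seconds` of every segment's EEG, envelope and mask, so
#' all pause conditions carry identical data durations into the CV.
#'
#' @param plan a [cv_plan()].
#' @param seconds duration to keep (the duration-matched analysis uses 120
#'   and 60 s).
#' @return the truncated `cv_plan`.
#' @export
truncate_for_duration_match <- function(plan, seconds) {
  stopifnot(inherits(plan, "cv_plan"))
  plan$segments <- lapply(lapply(plan$segments, align_segment),
                          truncate_segment, seconds = seconds)
  plan$truncation_s <- seconds
  plan
}

#' Pauses-removed decoding at one or more lag windows
#'
#' Excludes pause-labelled sample indices from the decoding on both sides
#' (design rows and target samples) and runs the CV, once per lag window
#' (the longer 0-500 ms window probes whether 0-300 ms suffices).
#'
#' @param segments as in [cv_plan()].
#' @param lag_windows list of `c(lag_min_ms, lag_max_ms)` pairs.
#' @param fs analysis rate, Hz.
#' @inheritParams cv_plan
#' @return tibble with one row per lag window plus list-column `result`.
#' @export
run_pauses_removed <- function(segments,
                               lag_windows = list(c(0, 300), c(0, 500)),
                               fs = 128,
                               lambda_grid = default_lambda_grid(),
                               subject = NA, condition = NA, band = NA) {
  res <- purrr::map(lag_windows, function(w) {
    run_cv(cv_plan(segments, lambda_grid,
                   spec = lag_spec(w[1], w[2], fs),
                   pauses_removed = TRUE,
                   subject = subject, condition = condition, band = band))
  })
  dplyr::bind_rows(lapply(res, glance)) |>
    dplyr::mutate(result = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
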