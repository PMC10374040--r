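# Significance machinery: per-recording permutation nulls built from
# mismatched envelope/EEG pairings, Friedman and Wilcoxon signed-rank
# comparisons, Bonferroni correction.

# all permutations of 1:n (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# Sample mismatched pairings. With few segments the derangement pool is
# tiny (9 permutations for n = 4), which leaves the null distribution with
# too few support points for a calibrated 95th-percentile test; in that
# case all non-identity permutations are enumerated and sampled instead.
# With n >= 5 the derangement pool is rich and derangements (no envelope
# paired with its own EEG) are preferred.
sample_pairings <- function(n, n_perm) {
  if (n < 2) stop("need >= 2 segments for a mismatched pairing")
  if (n <= 4) {
    pool <- all_permutations(n)[-1, , drop = FALSE]  # all non-identity
    pool[sample.int(nrow(pool), n_perm, replace = TRUE), , drop = FALSE]
  } else if (n <= 7) {
    perms <- all_permutations(n)
    fixed_free <- rowSums(perms == matrix(seq_len(n), nrow(perms), n,
                                          byrow = TRUE)) == 0
    pool <- perms[fixed_free, , drop = FALSE]
    pool[sample.int(nrow(pool), n_perm, replace = TRUE), , drop = FALSE]
  } else {
    t(vapply(seq_len(n_perm), function(i) {
      repeat {
        p <- sample.int(n)
        if (!any(p == seq_len(n))) return(p)
      }
    }, integer(n)))
  }
}

#' Permutation-null significance test for one recording cell
#'
#' Builds the null distribution of cross-validated reconstruction
#' correlations by pairing each EEG segment with a mismatched envelope
#' (derangement-preferring random pairings), in both training and testing,
#' and re-running the full cross-validation — including lambda selection —
#' for every permutation. All segments are truncated to the shortest
#' segment's length so any envelope can be paired with any EEG. The
#' observed (correctly paired) mean r is compared against the empirical
#' `(1 - alpha)` quantile of the null (quantile type "higher": the smallest
#' null value with at least `1 - alpha` of the null at or below it).
#'
#' @param segments as in [cv_plan()].
#' @param spec a [lag_spec()].
#' @param lambda_grid regularisation grid.
#' @param feature speech feature decoded (default `"full"`; for the full
#'   feature a fast sufficient-statistics path reuses the Cholesky factors
#'   across permutations).
#' @param n_perm number of permutations (default 500; fewer than 100 raises
#'   a quantile-instability warning).
#' @param alpha significance level.
#' @param seed RNG seed for the pairings.
#' @return object of class `permutation_null`: `null_r`, `critical_r`,
#'   `observed_r`, `significant`, plus settings.
#' @export
permutation_test <- function(segments, spec = lag_spec(),
                             lambda_grid = default_lambda_grid(),
                             feature = "full", n_perm = 500, alpha = 0.05,
                             seed = 1L) {
  if (length(segments) < 2) stop("need >= 2 segments")
  if (n_perm < 100) warning("n_perm < 100: null quantile may be unstable")
  segs <- lapply(segments, align_segment)
  L <- min(vapply(segs, function(s) length(s$envelope$values), integer(1)))
  segs <- lapply(segs, truncate_segment, seconds = L / segs[[1]]$envelope$fs)

  n_seg <- length(segs)
  nch <- nrow(segs[[1]]$eeg$data)
  M <- build_regularizer(spec, nch)
  n_lam <- length(lambda_grid)

  X <- lapply(segs, function(s) build_lagged_design(s$eeg, spec))
  y <- lapply(segs, function(s) s$envelope$values)
  valid <- lapply(segs, feature_valid, feature = feature)
  all_valid <- all(vapply(valid, all, logical(1)))

  # pairwise stats: EEG i against envelope j (rows restricted to j's
  # validity). In the all-valid case the design-side stats (A, cs) do not
  # depend on j, so Cholesky factors can be shared across permutations.
  st <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    st[[i]] <- vector("list", n_seg)
    if (all_valid) {
      A_i <- crossprod(X[[i]])
      cs_i <- colSums(X[[i]])
      for (j in seq_len(n_seg)) {
        st[[i]][[j]] <- list(
          n = L, cs = cs_i, A = A_i,
          b = as.numeric(crossprod(X[[i]], y[[j]])),
          ys = sum(y[[j]]), yss = sum(y[[j]]^2)
        )
      }
    } else {
      for (j in seq_len(n_seg)) {
        st[[i]][[j]] <- suff_stats(X[[i]], y[[j]], valid[[j]])
      }
    }
  }

  # per-fold cached factors (fast path only)
  cache <- NULL
  if (all_valid) {
    cache <- vector("list", n_seg)
    for (k in seq_len(n_seg)) {
      idx <- setdiff(seq_len(n_seg), k)
      A_tr <- Reduce(`+`, lapply(idx, function(i) st[[i]][[i]]$A))
      cs_tr <- Reduce(`+`, lapply(idx, function(i) st[[i]][[i]]$cs))
      n_tr <- L * length(idx)
      m <- cs_tr / n_tr
      A_c <- A_tr - n_tr * tcrossprod(m)
      chols <- lapply(lambda_grid, function(l) chol_safe(A_c + l * M))
      cache[[k]] <- list(m = m, n = n_tr, chols = chols)
    }
  }

  cv_for_pairing <- function(pairing) {
    fold_r <- matrix(NA_real_, n_seg, n_lam)
    for (k in seq_len(n_seg)) {
      idx <- setdiff(seq_len(n_seg), k)
      if (all_valid) {
        ck <- cache[[k]]
        b_tr <- Reduce(`+`, lapply(idx, function(i) st[[i]][[pairing[i]]]$b))
        ys_tr <- sum(vapply(idx, function(i) st[[i]][[pairing[i]]]$ys,
                            numeric(1)))
        ybar <- ys_tr / ck$n
        b_c <- b_tr - ck$n * ck$m * ybar
        te <- st[[k]][[pairing[k]]]
        # solve all lambdas into one matrix, then score them in bulk
        G <- vapply(seq_len(n_lam), function(j) {
          ch <- ck$chols[[j]]
          backsolve(ch, backsolve(ch, b_c, transpose = TRUE))
        }, numeric(length(b_c)))
        yk <- te$ys / te$n
        mk <- te$cs / te$n
        pg <- as.numeric(crossprod(mk, G))
        gAg <- colSums(G * (te$A %*% G))
        cov_term <- as.numeric(crossprod(te$b, G)) - te$n * pg * yk
        varp <- gAg - te$n * pg^2
        vart <- te$yss - te$n * yk^2
        r <- cov_term / sqrt(varp * vart)
        r[varp <= 0 | vart <= 0] <- NA_real_
        fold_r[k, ] <- r
      } else {
        tr <- add_stats(lapply(idx, function(i) st[[i]][[pairing[i]]]))
        gs <- fit_from_stats(tr, M, lambda_grid)
        te <- st[[k]][[pairing[k]]]
        m_train <- tr$cs / tr$n
        ybar <- tr$ys / tr$n
        for (j in seq_len(n_lam)) {
          fold_r[k, j] <- score_from_stats(gs[[j]], te, m_train, ybar)[["r"]]
        }
      }
    }
    mean_r <- colMeans(fold_r, na.rm = TRUE)
    mean_r[select_lambda_index(mean_r)]
  }

  observed_r <- cv_for_pairing(seq_len(n_seg))
  pairings <- withr::with_seed(seed, sample_pairings(n_seg, n_perm))
  null_r <- vapply(seq_len(n_perm),
                   function(i) cv_for_pairing(pairings[i, ]), numeric(1))

  critical_r <- sort(null_r)[ceiling((1 - alpha) * n_perm)]
  structure(
    list(null_r = null_r, critical_r = critical_r, observed_r = observed_r,
         significant = observed_r > critical_r, alpha = alpha,
         n_perm = n_perm, seed = seed, feature = feature,
         truncated_to_s = L / segs[[1]]$envelope$fs),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> observed r = %.4f vs critical r = %.4f (alpha = %g, %d perms): %s\n",
    x$observed_r, x$critical_r, x$alpha, x$n_perm,
    if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}

#' Friedman test across conditions
#'
#' Rank-based Friedman chi-square test for differences across related
#' conditions (columns) over subjects (rows); asymptotic p on `k - 1`
#' degrees of freedom. Accepts a subjects x conditions matrix or a long
#' data frame.
#'
#' @param data matrix (subjects x conditions) or long data frame.
#' @param value,condition,subject column names used when `data` is long.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `n_subjects`,
#'   `n_conditions`.
#' @export
friedman_rank_test <- function(data, value = "mean_r",
                               condition = "condition", subject = "subject") {
  if (!is.matrix(data)) {
    df <- as.data.frame(data)
    data <- stats::xtabs(stats::reformulate(c(subject, condition),
                                            response = value), data = df)
    data <- unclass(data)
  }
  if (anyNA(data)) stop("missing cells in the subjects x conditions matrix")
  if (nrow(data) < 2 || ncol(data) < 2) stop("need >= 2 subjects and conditions")
  ft <- stats::friedman.test(data)
  if (is.nan(ft$statistic)) {
    # fully tied ranks in every row: no evidence of any difference
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  tibble::tibble(
    statistic = unname(ft$statistic),
    df = unname(ft$parameter),
    p_value = ft$p.value,
    n_subjects = nrow(data),
    n_conditions = ncol(data)
  )
}

#' Wilcoxon signed-rank test for paired values
#'
#' Zero differences are dropped (Wilcoxon's original rule) and ties are
#' mid-ranked; the p-value is exact for `n <= 25` effective pairs without
#' ties, otherwise a normal approximation with continuity correction is
#' used. Two-sided by default. All-zero differences are a degenerate case,
#' returned flagged with `NA` p.
#'
#' @param x,y paired numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return one-row tibble: `w_plus`, `w_minus` (sums of positive / negative
#'   ranks), `p_value`, `n_effective`, `flagged`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("degenerate: all paired differences are zero")
    return(tibble::tibble(w_plus = NA_real_, w_minus = NA_real_,
                          p_value = NA_real_, n_effective = 0L,
                          flagged = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ties <- anyDuplicated(abs(d)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative,
    exact = (n <= 25 && !ties), correct = TRUE
  ))
  tibble::tibble(
    w_plus = w_plus, w_minus = w_minus,
    p_value = wt$p.value, n_effective = n, flagged = FALSE
  )
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level.
#' @param n_tests number of comparisons (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("`n_tests` must be >= 1")
  alpha / n_tests
}
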