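# Backward decoder: lagged design construction, the second-difference
# penalty, the regularised solve and scoring.

test_that("lagged design matches hand-constructed cases", {
  # 1 channel, lag 0 only: the design is the signal itself
  spec0 <- lag_spec(0, 0, fs = 1000)
  x <- matrix(c(5, 7, 11), 1, 3)
  expect_equal(build_lagged_design(x, spec0), matrix(c(5, 7, 11), 3, 1))

  # 1 channel, lags {0, 1} samples: rows [a,b],[b,c],[c,0] (zero-padded end)
  spec1 <- lag_spec(0, 1, fs = 1000)
  expect_equal(
    build_lagged_design(x, spec1),
    matrix(c(5, 7, 11, 7, 11, 0), 3, 2)
  )

  # 2 channels, lag 0: two columns equal to the channels
  x2 <- rbind(1:4, 5:8)
  expect_equal(build_lagged_design(x2, spec0),
               cbind(1:4, 5:8), ignore_attr = TRUE)
})

test_that("lag grid size follows the window and rate", {
  expect_equal(lag_spec(0, 300, 128)$n_lags, 39 + 1 - 1)  # 0..38 samples
  expect_equal(lag_spec(0, 500, 128)$n_lags, 65)
  expect_error(lag_spec(100, 50), "lag_min_ms")
})

test_that("regularizer has the tridiagonal block pattern and PSD structure", {
  spec <- lag_spec(0, 2 / 128 * 1000, 128)  # 3 lags
  expect_equal(spec$n_lags, 3L)
  M1 <- build_regularizer(spec, 1)
  expect_equal(M1, rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  # block diagonal across channels, no cross-channel coupling
  M2 <- build_regularizer(spec, 2)
  expect_equal(M2[1:3, 1:3], M1)
  expect_equal(M2[4:6, 4:6], M1)
  expect_equal(M2[1:3, 4:6], matrix(0, 3, 3))

  # annihilates the per-block constant vector; eigenvalues nonnegative
  expect_equal(as.numeric(M1 %*% rep(1, 3)), rep(0, 3))
  expect_true(all(eigen(M2, symmetric = TRUE)$values > -1e-12))

  # degenerate single-lag case: identity block
  expect_equal(build_regularizer(lag_spec(0, 0, 128), 2), diag(2))
})

test_that("identity regression recovers a unit weight", {
  set.seed(1)
  x <- matrix(rnorm(100), 1, 100)
  spec <- lag_spec(0, 0, 128)
  design <- build_lagged_design(x, spec)
  fit <- fit_decoder(design, as.numeric(x), lambda = 0, spec = spec,
                     n_channels = 1)
  expect_equal(fit$g, 1, tolerance = 1e-10)
  expect_equal(reconstruct(fit, design, center = TRUE), as.numeric(x),
               tolerance = 1e-10)
})

test_that("fit matches the brute-force normal-equations oracle", {
  set.seed(7)
  for (rep in 1:10) {
    inst <- random_decoder_instance(
      n = sample(100:500, 1),
      n_channels = sample(1:3, 1),
      n_lags = sample(2:5, 1)
    )
    for (lambda in c(0.01, 2.5, 1e6)) {
      fit <- fit_decoder(inst$design, inst$target, lambda, M = inst$M,
                         spec = inst$spec, n_channels = inst$n_channels)
      g0 <- oracle_decoder(inst$design, inst$target, lambda, inst$M)
      expect_lt(max(abs(fit$g - g0)), 1e-8)
    }
  }
})

test_that("masked fitting equals fitting on the row-deleted system", {
  set.seed(11)
  inst <- random_decoder_instance(n = 300, n_channels = 2, n_lags = 4)
  mask <- runif(300) > 0.3
  fit_masked <- fit_decoder(inst$design, inst$target, 1.5, M = inst$M,
                            spec = inst$spec, n_channels = inst$n_channels,
                            mask = mask)
  fit_deleted <- fit_decoder(inst$design[mask, ], inst$target[mask], 1.5,
                             M = inst$M, spec = inst$spec,
                             n_channels = inst$n_channels)
  expect_equal(fit_masked$g, fit_deleted$g, tolerance = 1e-12)

  # NA-style exclusion behaves the same as the logical mask
  y_na <- inst$target
  y_na[!mask] <- NA
  fit_na <- fit_decoder(inst$design, y_na, 1.5, M = inst$M,
                        spec = inst$spec, n_channels = inst$n_channels)
  expect_equal(fit_na$g, fit_deleted$g, tolerance = 1e-12)
})

test_that("scaling the target scales weights and leaves r unchanged", {
  set.seed(13)
  inst <- random_decoder_instance(n = 250, n_channels = 2, n_lags = 3)
  fit1 <- fit_decoder(inst$design, inst$target, 2, M = inst$M,
                      spec = inst$spec, n_channels = inst$n_channels)
  fit3 <- fit_decoder(inst$design, 3 * inst$target, 2, M = inst$M,
                      spec = inst$spec, n_channels = inst$n_channels)
  expect_equal(fit3$g, 3 * fit1$g, tolerance = 1e-10)
  s1 <- score_reconstruction(reconstruct(fit1, inst$design), inst$target)
  s3 <- score_reconstruction(reconstruct(fit3, inst$design), 3 * inst$target)
  expect_equal(s1$pearson_r, s3$pearson_r, tolerance = 1e-12)
})

test_that("penalty energy shrinks monotonically in lambda and weights
           approach the penalty null space at extreme lambda", {
  set.seed(17)
  inst <- random_decoder_instance(n = 400, n_channels = 2, n_lags = 5)
  lambdas <- c(0.01, 1, 100, 1e6, 1e12)
  energy <- vapply(lambdas, function(l) {
    g <- fit_decoder(inst$design, inst$target, l, M = inst$M,
                     spec = inst$spec, n_channels = inst$n_channels)$g
    as.numeric(crossprod(g, inst$M %*% g))
  }, numeric(1))
  expect_true(all(diff(energy) <= 1e-10))
  # at lambda = 1e12 the weights are constant across lags within channel
  # (the penalty null space), not zero in general
  g_inf <- fit_decoder(inst$design, inst$target, 1e12, M = inst$M,
                       spec = inst$spec, n_channels = inst$n_channels)$g
  w <- matrix(g_inf, inst$spec$n_lags, inst$n_channels)
  expect_lt(max(abs(sweep(w, 2, colMeans(w)))), 1e-6)
})

test_that("reconstruction is linear and scoring handles hand cases", {
  set.seed(19)
  inst <- random_decoder_instance(n = 120, n_channels = 1, n_lags = 3)
  f1 <- fit_decoder(inst$design, inst$target, 1, M = inst$M,
                    spec = inst$spec, n_channels = 1)
  f2 <- fit_decoder(inst$design, rev(inst$target), 1, M = inst$M,
                    spec = inst$spec, n_channels = 1)
  fsum <- f1
  fsum$g <- f1$g + f2$g
  expect_equal(reconstruct(fsum, inst$design),
               reconstruct(f1, inst$design) + reconstruct(f2, inst$design),
               tolerance = 1e-12)
  zero <- f1
  zero$g <- rep(0, length(f1$g))
  expect_equal(reconstruct(zero, inst$design), rep(0, 120))

  # hand-computed score: S = 1:4, S_hat = 2*S
  sc <- score_reconstruction(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(sc$pearson_r, 1)
  expect_equal(sc$mse, mean(c(1, 4, 9, 16)))
  expect_equal(score_reconstruction(-(1:4), 1:4)$pearson_r, -1)

  # degenerate scores are flagged, not silently zero
  expect_warning(out <- score_reconstruction(c(1, 1, 1, 1), c(1, 2, 3, 4)))
  expect_true(out$flagged)
  expect_true(is.na(out$pearson_r))
})

test_that("singular unregularised systems error with advice", {
  x <- matrix(rnorm(50), 1, 50)
  spec <- lag_spec(0, 0, 128)
  design <- build_lagged_design(x, spec)
  design2 <- cbind(design, design)  # exactly collinear
  M <- diag(2)
  expect_error(fit_decoder(design2, rnorm(50), 0, M = M, n_channels = 2),
               "lambda > 0")
})

test_that("tidy and glance return the expected shapes", {
  set.seed(23)
  inst <- random_decoder_instance(n = 100, n_channels = 2, n_lags = 3)
  fit <- fit_decoder(inst$design, inst$target, 1, M = inst$M,
                     spec = inst$spec, n_channels = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_named(td, c("lag_ms", "channel", "weight"))
  gl <- glance(fit)
  expect_equal(gl$n_lags, 3)
  expect_equal(gl$lambda, 1)
})
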