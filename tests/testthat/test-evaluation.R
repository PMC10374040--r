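# Cross-validated evaluation: fold structure, lambda selection, feature
# grid, duration matching, pauses-removed decoding.

test_that("leave-one-out produces one fold per segment and matches a direct fit", {
  cfg <- tiny_config(n_segments_per_condition = 4)
  segs <- make_cell_segments(cfg, "natural", "delta")
  grid <- c(0.1, 10, 1000)
  res <- run_cv(cv_plan(segs, lambda_grid = grid))
  expect_equal(nrow(res$fold), 4)
  expect_true(res$selected_lambda %in% grid)

  # reproduce fold 1 by hand with fit_decoder on concatenated designs
  spec <- lag_spec()
  segs_al <- lapply(segs, pausetrack:::align_segment)
  designs <- lapply(segs_al, function(s) build_lagged_design(s$eeg, spec))
  X_tr <- do.call(rbind, designs[2:4])
  y_tr <- unlist(lapply(segs_al[2:4], function(s) s$envelope$values))
  nch <- nrow(segs_al[[1]]$eeg$data)
  fit <- fit_decoder(X_tr, y_tr, res$selected_lambda, spec = spec,
                     n_channels = nch)
  pred <- reconstruct(fit, designs[[1]], center = TRUE)
  sc <- score_reconstruction(pred, segs_al[[1]]$envelope$values)
  expect_equal(res$fold$pearson_r[1], sc$pearson_r, tolerance = 1e-8)
  expect_equal(res$fold$mse[1], sc$mse, tolerance = 1e-8)
})

test_that("noiseless sustained-response data is reconstructed almost perfectly", {
  cfg <- tiny_config(snr_db = Inf, onset_gain = 0, sustained_gain = 1)
  segs <- make_cell_segments(cfg, "natural", "delta")
  res <- run_cv(cv_plan(segs))
  expect_gt(res$mean_r, 0.95)
})

test_that("lambda ties resolve to the smaller value", {
  expect_equal(pausetrack:::select_lambda_index(c(0.5, 0.5, 0.4)), 1)
  expect_equal(pausetrack:::select_lambda_index(c(0.3, 0.5, 0.5 - 1e-13)), 2)
  expect_equal(pausetrack:::select_lambda_index(c(0.3, NA, 0.5)), 3)
})

test_that("segment order does not change the selected lambda or mean r", {
  cfg <- tiny_config()
  segs <- make_cell_segments(cfg, "short", "delta")
  r1 <- run_cv(cv_plan(segs))
  r2 <- run_cv(cv_plan(segs[c(3, 1, 4, 2)]))
  expect_equal(r1$selected_lambda, r2$selected_lambda)
  expect_equal(r1$mean_r, r2$mean_r, tolerance = 1e-12)
  expect_equal(sort(r1$fold$pearson_r), sort(r2$fold$pearson_r),
               tolerance = 1e-12)
})

test_that("feature grid diagonal reproduces run_cv and shares folds", {
  cfg <- tiny_config(onset_gain = 3)
  segs <- make_cell_segments(cfg, "short", "delta")
  grid <- default_lambda_grid(15)
  fg <- feature_grid(segs, lambda_grid = grid)
  expect_equal(nrow(fg), 9)

  direct <- run_cv(cv_plan(segs, lambda_grid = grid,
                           train_feature = "onsets",
                           test_feature = "onsets"))
  cell <- dplyr::filter(fg, train_feature == "onsets",
                        test_feature == "onsets")
  expect_equal(cell$mean_r, direct$mean_r, tolerance = 1e-10)
  expect_equal(cell$selected_lambda, direct$selected_lambda)
})

test_that("duration-matched truncation keeps exactly the requested samples", {
  cfg <- tiny_config()
  segs <- make_cell_segments(cfg, "long", "delta")
  plan <- cv_plan(segs)
  plan10 <- truncate_for_duration_match(plan, 10)
  for (s in plan10$segments) {
    expect_equal(length(s$envelope$values), 10 * 128)
    expect_equal(ncol(s$eeg$data), 10 * 128)
  }
  # identity when truncating to the full (minimum) length
  n_min <- min(vapply(plan$segments,
                      function(s) length(pausetrack:::align_segment(s)$envelope$values),
                      integer(1)))
  plan_id <- truncate_for_duration_match(plan, n_min / 128)
  expect_equal(length(plan_id$segments[[1]]$envelope$values), n_min)
  # over-truncation errors
  expect_error(truncate_for_duration_match(plan, 10000), "shorter")
  # truncated conditions carry equal training data regardless of condition
  segs_nat <- make_cell_segments(cfg, "natural", "delta")
  p1 <- truncate_for_duration_match(cv_plan(segs_nat), 10)
  expect_equal(length(p1$segments[[1]]$envelope$values),
               length(plan10$segments[[1]]$envelope$values))
})

test_that("pauses-removed decoding equals full decoding when no pauses exist", {
  cfg <- tiny_config()
  segs <- make_cell_segments(cfg, "natural", "delta")
  # overwrite masks: declare everything speech
  segs_nopause <- lapply(segs, function(s) {
    s$mask$labels <- rep("non_onset", length(s$mask$labels))
    s
  })
  grid <- default_lambda_grid(10)
  res_full <- run_cv(cv_plan(segs_nopause, lambda_grid = grid))
  res_pr <- run_cv(cv_plan(segs_nopause, lambda_grid = grid,
                           pauses_removed = TRUE))
  expect_equal(res_pr$mean_r, res_full$mean_r, tolerance = 1e-12)
  expect_equal(res_pr$fold$pearson_r, res_full$fold$pearson_r,
               tolerance = 1e-12)

  # the lag-window variants are labelled correctly
  pr <- run_pauses_removed(segs, lag_windows = list(c(0, 300), c(0, 500)),
                           lambda_grid = grid)
  expect_equal(pr$lag_max_ms, c(300, 500))
  expect_true(all(pr$pauses_removed))
})

test_that("masked-row exclusion in the CV equals physical row deletion", {
  cfg <- tiny_config()
  segs <- make_cell_segments(cfg, "short", "delta")
  grid <- c(1, 100)
  spec <- lag_spec()
  # onsets-feature CV via masks
  res_mask <- run_cv(cv_plan(segs, lambda_grid = grid,
                             train_feature = "onsets",
                             test_feature = "onsets"))
  # same computation with rows physically deleted from design and target
  segs_al <- lapply(segs, pausetrack:::align_segment)
  nch <- nrow(segs_al[[1]]$eeg$data)
  M <- build_regularizer(spec, nch)
  Xs <- lapply(segs_al, function(s) {
    X <- build_lagged_design(s$eeg, spec)
    keep <- s$mask$labels == "onset"
    list(X = X[keep, , drop = FALSE], y = s$envelope$values[keep])
  })
  fold_r <- sapply(seq_along(Xs), function(k) {
    X_tr <- do.call(rbind, lapply(Xs[-k], `[[`, "X"))
    y_tr <- unlist(lapply(Xs[-k], `[[`, "y"))
    sapply(grid, function(l) {
      fit <- fit_decoder(X_tr, y_tr, l, M = M, spec = spec, n_channels = nch)
      sc <- score_reconstruction(reconstruct(fit, Xs[[k]]$X, center = TRUE),
                                 Xs[[k]]$y)
      sc$pearson_r
    })
  })
  mean_r <- rowMeans(fold_r)
  sel <- which.max(mean_r)
  expect_equal(res_mask$mean_r, mean_r[sel], tolerance = 1e-10)
  expect_equal(res_mask$selected_lambda, grid[sel])
})

test_that("more training data does not hurt on average across subjects", {
  # paired one-sided comparison across 20 simulated subjects: there must be
  # no evidence that longer recordings reduce reconstruction accuracy
  cfg <- tiny_config(n_subjects = 20, words_per_segment = 100, snr_db = -10)
  diffs <- vapply(1:20, function(subj) {
    segs <- make_cell_segments(cfg, "natural", "delta", subject = subj)
    plan <- cv_plan(segs, lambda_grid = default_lambda_grid(10))
    r_more <- run_cv(truncate_for_duration_match(plan, 40))$mean_r
    r_less <- run_cv(truncate_for_duration_match(plan, 6))$mean_r
    r_more - r_less
  }, numeric(1))
  hurts <- stats::t.test(diffs, alternative = "less")
  expect_gt(hurts$p.value, 0.05)
})

test_that("eval results tidy and glance into tables", {
  cfg <- tiny_config()
  segs <- make_cell_segments(cfg, "natural", "delta")
  res <- run_cv(cv_plan(segs, lambda_grid = c(1, 100), subject = 1,
                        condition = "natural", band = "delta"))
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  expect_true(all(c("fold", "pearson_r", "mse", "condition") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$condition, "natural")
  expect_s3_class(autoplot(res), "ggplot")
})
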