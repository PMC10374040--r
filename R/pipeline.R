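# Config-driven orchestration: simulate -> preprocess -> segment ->
# evaluate -> infer, producing tidy, figure-ready result tables (mean r
# +/- 95% CI per condition/band, feature-grid tables, duration-matched and
# pauses-removed analyses, permutation significance).

#' Study run configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param bands EEG bands to analyse.
#' @param conditions pause conditions to analyse.
#' @param features speech features crossed in the decoder grid.
#' @param fs_out analysis rate, Hz.
#' @param lag_min_ms,lag_max_ms decoder lag window, milliseconds.
#' @param lambda_grid regularisation grid.
#' @param mask_source `"ground_truth"` (generator pause intervals) or
#'   `"detect"` (threshold detection on the broadband envelope).
#' @param threshold_frac,min_pause_ms,onset_window_ms segmentation
#'   parameters (see [detect_pauses()]).
#' @param truncations segment truncations for the duration-matched analysis,
#'   seconds (e.g. `c(120, 60)`); `NULL` to skip.
#' @param pauses_removed run the pauses-removed decoding analysis?
#' @param pauses_removed_lags lag windows for it, list of ms pairs.
#' @param n_perm permutations per recording for significance (0 = skip).
#' @param alpha significance level.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       bands = c("delta", "theta"),
                       conditions = c("natural", "short", "long"),
                       features = c("full", "onsets", "non_onsets"),
                       fs_out = 128,
                       lag_min_ms = 0, lag_max_ms = 300,
                       lambda_grid = default_lambda_grid(),
                       mask_source = c("ground_truth", "detect"),
                       threshold_frac = 0.01, min_pause_ms = 100,
                       onset_window_ms = 150,
                       truncations = NULL,
                       pauses_removed = FALSE,
                       pauses_removed_lags = list(c(0, 300), c(0, 500)),
                       n_perm = 0, alpha = 0.05) {
  mask_source <- match.arg(mask_source)
  bands <- match.arg(bands, c("delta", "theta"), several.ok = TRUE)
  conditions <- match.arg(conditions, c("natural", "short", "long"),
                          several.ok = TRUE)
  stopifnot(inherits(sim, "sim_config"))
  structure(
    list(sim = sim, bands = bands, conditions = conditions,
         features = features, fs_out = fs_out,
         lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms,
         lambda_grid = lambda_grid, mask_source = mask_source,
         threshold_frac = threshold_frac, min_pause_ms = min_pause_ms,
         onset_window_ms = onset_window_ms, truncations = truncations,
         pauses_removed = pauses_removed,
         pauses_removed_lags = pauses_removed_lags,
         n_perm = n_perm, alpha = alpha),
    class = "run_config"
  )
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `sim` block
#' mirrors [sim_config()].
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- do.call(sim_config, sim_args)
  if (!is.null(raw$lambda_grid)) {
    raw$lambda_grid <- do.call(default_lambda_grid, as.list(raw$lambda_grid))
  }
  do.call(run_config, raw)
}

# Simulate, preprocess and segment one (subject, condition) cell for one
# band; returns the segments list consumed by cv_plan().
prepare_cell_segments <- function(config, subject, condition, band) {
  n_seg <- config$sim$n_segments_per_condition
  lapply(seq_len(n_seg), function(seg_i) {
    rec <- simulate_recording(config$sim, subject, seg_i, condition)
    eeg <- preprocess_eeg(rec$eeg, band, config$fs_out)
    env <- bandlimit_envelope(rec$envelope, band, config$fs_out)
    n <- min(length(env$values), ncol(eeg$data))
    mask <- if (config$mask_source == "ground_truth") {
      mask_from_ground_truth(rec$pause_intervals, n, config$fs_out,
                             config$onset_window_ms)
    } else {
      bb <- downsample_envelope(rec$envelope, config$fs_out)
      bb$values <- bb$values[seq_len(min(n, length(bb$values)))]
      detect_pauses(bb, config$threshold_frac, config$min_pause_ms,
                    config$onset_window_ms)
    }
    list(eeg = eeg, envelope = env, mask = mask)
  })
}

#' Run the full study on synthetic data
#'
#' Executes simulate -> preprocess -> segment -> evaluate -> infer for every
#' (subject, condition, band) cell: the train x test feature grid, optional
#' duration-matched truncations, optional pauses-removed decoding, optional
#' per-recording permutation significance, and the group-level Friedman /
#' Wilcoxon comparison tables with Bonferroni-adjusted levels. Deterministic
#' given the seeds in `config`.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for tidy CSV outputs and a JSON
#'   manifest.
#' @param verbose print per-stage progress?
#' @return object of class `study_result`: tibbles `results` (one row per
#'   cell), `truncation_results`, `pauses_removed_results`, `permutation`,
#'   `friedman`, `wilcoxon_features`, plus the resolved `config`.
#' @export
run_full_study <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  spec <- lag_spec(config$lag_min_ms, config$lag_max_ms, config$fs_out)
  subjects <- seq_len(config$sim$n_subjects)

  results <- list()
  trunc_results <- list()
  pr_results <- list()
  perm_rows <- list()

  run_stage <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  for (subject in subjects) {
    for (condition in config$conditions) {
      for (band in config$bands) {
        if (verbose) {
          message(sprintf("subject %d | %s | %s", subject, condition, band))
        }
        segs <- run_stage(
          prepare_cell_segments(config, subject, condition, band),
          "simulate/preprocess/segment"
        )
        key <- sprintf("S%02d_%s_%s", subject, condition, band)
        results[[key]] <- run_stage(
          feature_grid(segs, config$lambda_grid, spec,
                       features = config$features,
                       subject = subject, condition = condition,
                       band = band) |>
            dplyr::select(-"result"),
          "evaluate"
        )
        for (tr_s in config$truncations) {
          plan <- cv_plan(segs, config$lambda_grid, spec,
                          subject = subject, condition = condition,
                          band = band)
          plan <- truncate_for_duration_match(plan, tr_s)
          trunc_results[[paste(key, tr_s)]] <- glance(run_cv(plan))
        }
        if (config$pauses_removed) {
          pr_results[[key]] <- run_pauses_removed(
            segs, config$pauses_removed_lags, config$fs_out,
            config$lambda_grid, subject = subject, condition = condition,
            band = band
          ) |> dplyr::select(-"result")
        }
        if (config$n_perm > 0) {
          pt <- run_stage(
            permutation_test(segs, spec, config$lambda_grid,
                             n_perm = config$n_perm, alpha = config$alpha,
                             seed = stream_seed(config$sim$seed, subject,
                                                99L, condition)),
            "permutation"
          )
          perm_rows[[key]] <- tibble::tibble(
            subject = subject, condition = condition, band = band,
            observed_r = pt$observed_r, critical_r = pt$critical_r,
            significant = pt$significant
          )
        }
      }
    }
  }

  results <- dplyr::bind_rows(results)
  out <- structure(
    list(
      results = results,
      truncation_results = dplyr::bind_rows(trunc_results),
      pauses_removed_results = dplyr::bind_rows(pr_results),
      permutation = dplyr::bind_rows(perm_rows),
      friedman = condition_friedman_table(results),
      wilcoxon_features = feature_wilcoxon_table(results,
                                                 alpha = config$alpha),
      config = config
    ),
    class = "study_result"
  )
  if (!is.null(out_dir)) write_study_result(out, out_dir)
  out
}

# Friedman test across pause conditions within each (band, train, test)
# cell, Bonferroni-adjusted across the conditions compared.
condition_friedman_table <- function(results, alpha = 0.05) {
  if (length(unique(results$condition)) < 2) return(tibble::tibble())
  results |>
    dplyr::group_by(.data$band, .data$train_feature, .data$test_feature) |>
    dplyr::group_modify(function(df, key) {
      friedman_rank_test(df, value = "mean_r")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      alpha_adjusted = bonferroni_alpha(alpha, dplyr::n_distinct(
        results$condition)),
      significant = .data$p_value <= .data$alpha_adjusted
    )
}

# Pairwise Wilcoxon signed-rank tests between test features (decoder
# trained on the full envelope), per band and condition; the Bonferroni
# adjustment counts all feature-pair tests in a band.
feature_wilcoxon_table <- function(results, alpha = 0.05) {
  sub <- dplyr::filter(results, .data$train_feature == "full")
  feats <- unique(sub$test_feature)
  if (length(feats) < 2 || !nrow(sub)) return(tibble::tibble())
  pairs <- utils::combn(feats, 2, simplify = FALSE)
  grid <- tidyr::expand_grid(
    band = unique(sub$band), condition = unique(sub$condition),
    pair = pairs
  )
  n_tests <- nrow(grid)
  purrr::pmap_dfr(grid, function(band, condition, pair) {
    a <- dplyr::filter(sub, .data$band == !!band,
                       .data$condition == !!condition,
                       .data$test_feature == pair[1]) |>
      dplyr::arrange(.data$subject)
    b <- dplyr::filter(sub, .data$band == !!band,
                       .data$condition == !!condition,
                       .data$test_feature == pair[2]) |>
      dplyr::arrange(.data$subject)
    wt <- wilcoxon_signed_rank(a$mean_r, b$mean_r)
    tibble::tibble(
      band = band, condition = condition,
      feature_a = pair[1], feature_b = pair[2],
      p_value = wt$p_value,
      alpha_adjusted = bonferroni_alpha(alpha, n_tests),
      significant = !is.na(wt$p_value) & wt$p_value <= bonferroni_alpha(
        alpha, n_tests)
    )
  })
}

write_study_result <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (nrow(df)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(study$results, "results")
  wr(study$truncation_results, "truncation_results")
  wr(study$pauses_removed_results, "pauses_removed_results")
  wr(study$permutation, "permutation")
  wr(study$friedman, "friedman")
  wr(study$wilcoxon_features, "wilcoxon_features")
  cfg <- study$config
  manifest <- list(
    sim = unclass(cfg$sim),
    bands = cfg$bands, conditions = cfg$conditions,
    features = cfg$features, fs_out = cfg$fs_out,
    lag_window_ms = c(cfg$lag_min_ms, cfg$lag_max_ms),
    lambda_grid_range = range(cfg$lambda_grid),
    lambda_grid_n = length(cfg$lambda_grid),
    mask_source = cfg$mask_source, truncations = cfg$truncations,
    pauses_removed = cfg$pauses_removed, n_perm = cfg$n_perm,
    alpha = cfg$alpha
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "<study_result> %d cells (%d subjects x %s x %s)\n",
    nrow(x$results), x$config$sim$n_subjects,
    paste(x$config$conditions, collapse = "/"),
    paste(x$config$bands, collapse = "/")
  ))
  invisible(x)
}

# t-based 95% confidence interval for a mean
mean_ci <- function(x, level = 0.95) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  if (n < 2) return(c(mean = m, lower = NA_real_, upper = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x, na.rm = TRUE) /
    sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Summarise and plot a study result
#'
#' Cohort summary (mean r with 95% t-intervals per band, condition and
#' feature cell), the comparison tables, condition-wise plots, and — when a
#' permutation analysis was run — per-subject significance flags (cells
#' whose observed r does not exceed their permutation critical value).
#'
#' @param study a `study_result`.
#' @param out_dir optional directory for summary CSVs.
#' @return list with `summary` (tibble), `friedman`, `wilcoxon_features`,
#'   `nonsignificant_cells` (tibble, possibly empty), and `plots` (list of
#'   ggplot objects).
#' @export
make_report <- function(study, out_dir = NULL) {
  stopifnot(inherits(study, "study_result"))
  if (!nrow(study$results)) stop("incomplete result bundle: no cell results")
  summary <- study$results |>
    dplyr::group_by(.data$band, .data$condition, .data$train_feature,
                    .data$test_feature) |>
    dplyr::summarise(
      n = dplyr::n(),
      ci = list(mean_ci(.data$mean_r)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("ci") |>
    dplyr::rename(mean_r = "mean")

  nonsig <- if (nrow(study$permutation)) {
    dplyr::filter(study$permutation, !.data$significant)
  } else {
    tibble::tibble()
  }

  plots <- list(condition_means = autoplot.study_result(study))

  out <- list(summary = summary, friedman = study$friedman,
              wilcoxon_features = study$wilcoxon_features,
              nonsignificant_cells = nonsig, plots = plots)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}
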