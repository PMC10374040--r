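# ggplot2 figure methods for the result types.

#' Plot cohort mean reconstruction accuracy by pause condition
#'
#' Mean Pearson r with 95% t-intervals, one panel per band, coloured by the
#' test feature (decoders trained on the full envelope).
#'
#' @param object a `study_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.study_result <- function(object, ...) {
  df <- object$results |>
    dplyr::filter(.data$train_feature == "full") |>
    dplyr::group_by(.data$band, .data$condition, .data$test_feature) |>
    dplyr::summarise(ci = list(mean_ci(.data$mean_r)), .groups = "drop") |>
    tidyr::unnest_wider("ci")
  df$condition <- factor(df$condition, c("natural", "short", "long"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition, y = .data$mean,
    colour = .data$test_feature, group = .data$test_feature
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.15, position = ggplot2::position_dodge(0.3)
    ) +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "pause condition", y = "mean reconstruction r",
                  colour = "tested on") +
    ggplot2::theme_minimal()
}

#' Plot the lambda profile of a cross-validation run
#'
#' Mean fold correlation against the regularisation grid, with the selected
#' lambda marked.
#'
#' @param object an `eval_result`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_result <- function(object, ...) {
  ggplot2::ggplot(object$by_lambda,
                  ggplot2::aes(x = .data$lambda, y = .data$mean_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_lambda,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "mean fold r") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the null correlations with the critical and observed values
#' marked.
#'
#' @param object a `permutation_null`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.permutation_null <- function(object, ...) {
  df <- tibble::tibble(null_r = object$null_r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$critical_r,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed_r, colour = "red") +
    ggplot2::labs(x = "null mean r", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot onset / non-onset amplitude histograms
#'
#' @param hist_df output of [amplitude_histogram()].
#' @export
plot_amplitude_histogram <- function(hist_df) {
  ggplot2::ggplot(hist_df, ggplot2::aes(
    x = .data$bin_mid, y = .data$count, fill = .data$label
  )) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "envelope amplitude", y = "sample count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a modulation spectrum
#'
#' @param spec_df tibble from [modulation_spectrum()], optionally with a
#'   `condition` column for overlaying several spectra.
#' @export
plot_modulation_spectrum <- function(spec_df) {
  aes <- if ("condition" %in% names(spec_df)) {
    ggplot2::aes(x = .data$frequency, y = .data$power,
                 colour = .data$condition)
  } else {
    ggplot2::aes(x = .data$frequency, y = .data$power)
  }
  ggplot2::ggplot(spec_df, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "modulation frequency (Hz)", y = "normalised power") +
    ggplot2::theme_minimal()
}
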