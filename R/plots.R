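# ggplot2 visualizations for the pipeline's result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.psd_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD~(mu*V^2/Hz)),
                  title = sprintf("Welch PSD (%g s windows, %d averaged)",
                                  object$window_s, object$n_segments)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.electrode_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(as.data.frame(object), dplyr::all_of(PAIR_COLUMNS),
                            names_to = "pair", values_to = "p")
  df$pair <- sub("^p_", "", df$pair)
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$p,
                                   shape = .data$pair,
                                   colour = .data$verdict)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Tukey-adjusted p",
                  title = sprintf("Electrode selection (%s, %s)",
                                  attr(object, "subject_id") %||% "?",
                                  attr(object, "measure") %||% "?")) +
    ggplot2::theme_minimal()
}

#' Bar chart of electrode adoption frequency
#'
#' @param freq Output of [selection_frequency()].
#' @return A ggplot.
#' @export
plot_selection_frequency <- function(freq) {
  freq$channel <- factor(freq$channel, levels = freq$channel)
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$channel, y = .data$n_adopted)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Adoptions",
                  title = "Electrode adoption across subjects and measures") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "n")
  df <- df |>
    dplyr::group_by(.data$true) |>
    dplyr::mutate(rate = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s confusion (mean accuracy %.3f)",
                                  object$scheme, object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Per-label feature distributions of a feature table
#'
#' @param ft A `feature_table`.
#' @return A ggplot of per-channel, per-label feature distributions.
#' @export
plot_feature_distributions <- function(ft) {
  df <- tidyr::pivot_longer(as.data.frame(ft),
                            dplyr::all_of(feature_channels(ft)),
                            names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$value,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = sprintf("%s (normalized)",
                                        attr(ft, "measure") %||% "feature")) +
    ggplot2::theme_minimal()
}
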