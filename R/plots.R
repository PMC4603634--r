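#' Plot a chance-level calibration curve
#'
#' Mean CSMF accuracy of Random Allocation against cause-list length, with a
#' Monte Carlo error ribbon and the asymptote `1 - exp(-1)` marked.
#'
#' @param object A [calibration_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$j, y = .data$mean_csmf_accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_csmf_accuracy - 2 * .data$se_csmf_accuracy,
        ymax = .data$mean_csmf_accuracy + 2 * .data$se_csmf_accuracy
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = asymptotic_chance_constant(), linetype = "dashed") +
    ggplot2::labs(
      x = "Cause-list length J",
      y = "Mean CSMF accuracy of random allocation",
      caption = sprintf("dashed line: 1 - exp(-1) = %.4f", asymptotic_chance_constant())
    ) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo vs analytic chance-level concordance
#'
#' @param object A [calibration_curve()] result.
#' @param ... Unused.
#' @return A ggplot object comparing the Monte Carlo mean concordance of
#'   Random Allocation with the analytic value `1/J`.
#' @export
plot_concordance_check <- function(object, ...) {
  stopifnot(inherits(object, "calibration_curve"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$analytic_concordance, y = .data$mean_concordance)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Analytic chance concordance 1/J",
      y = "Monte Carlo mean concordance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the baseline-scheme comparison
#'
#' @param object A [compare_baseline_schemes()] result.
#' @param ... Unused.
#' @return A ggplot object: mean CCCSMF per scheme across cause-list lengths.
#' @export
autoplot.scheme_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$j, y = .data$mean_cccsmf, colour = .data$scheme)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Cause-list length J", y = "Mean CCCSMF accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot of the counts (rows = true causes).
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  long <- tidy.confusion_matrix(object)
  long$true_cause <- factor(long$true_cause, levels = rev(as.character(object$causes)))
  long$predicted_cause <- factor(long$predicted_cause, levels = as.character(object$causes))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted_cause, y = .data$true_cause,
                                     fill = .data$n, label = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Predicted cause", y = "True cause", fill = "Deaths") +
    ggplot2::theme_minimal()
}

#' Histogram of per-replicate CCCSMF values
#'
#' @param object A [evaluate_with_resampling()] result.
#' @param metric Which per-replicate metric to plot.
#' @param ... Unused.
#' @return A ggplot histogram with the replicate mean marked.
#' @export
autoplot.resampling_summary <- function(object, metric = c("cccsmf_accuracy", "csmf_accuracy", "ccc"), ...) {
  metric <- match.arg(metric)
  vals <- object$replicates[[metric]]
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = mean(vals), colour = "red") +
    ggplot2::labs(x = metric, y = "Replicates") +
    ggplot2::theme_minimal()
}
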