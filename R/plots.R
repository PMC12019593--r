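#' Plot sorted sensor response curves of a sample set
#'
#' Each sample is drawn as one line over its sensors sorted from most to
#' least active, colored by analyte class — the standard view for comparing
#' dynamic-range structure between the concentration and saturation
#' datasets.
#'
#' @param object An `hq_samples` tibble.
#' @param normalized Plot l1-normalized responses instead of raw (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hq_samples <- function(object, normalized = FALSE, ...) {
  resp <- sample_matrix(object)
  if (normalized) resp <- t(apply(resp, 1, normalize_l1))
  sorted <- t(apply(resp, 1, sort, decreasing = TRUE))
  df <- tibble::tibble(
    sample = rep(seq_len(nrow(sorted)), times = ncol(sorted)),
    rank = rep(seq_len(ncol(sorted)), each = nrow(sorted)),
    response = as.vector(sorted),
    analyte = factor(rep(object$label, times = ncol(sorted)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$response,
                                   group = .data$sample,
                                   colour = .data$analyte)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "sensor (sorted by activation)",
                  y = if (normalized) "normalized response" else "response",
                  colour = "analyte",
                  title = paste(attr(object, "dataset_tag"), "dataset")) +
    ggplot2::theme_minimal()
}

#' Plot the detection thresholds of a quantization scheme
#'
#' Shows where each MC column's detection thresholds sit in the normalized
#' input range — equidistant for the uniform condition, range-fitted for
#' scaled, density-fitted for adaptive.
#'
#' @param scheme An `hq_scheme`.
#' @return A ggplot object.
#' @export
plot_scheme <- function(scheme) {
  df <- tidy(scheme)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$sensor), .data$threshold)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "sensor column", y = "detection threshold",
                  title = paste(scheme$condition, "scheme, duplication",
                                scheme$duplication)) +
    ggplot2::theme_minimal()
}

#' Plot summarized accuracy and regularization across design cells
#'
#' @param object An `hq_report` from [report_runs()].
#' @param metric `"accuracy"` (mean with 95% CI) or `"regularization"`
#'   (mean utilization standard deviation).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hq_report <- function(object, metric = c("accuracy",
                                                  "regularization"), ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, .data$layer != "et" |
                        metric == "accuracy")
  if (metric == "accuracy") {
    p <- ggplot2::ggplot(df, ggplot2::aes(factor(.data$duplication),
                                          .data$accuracy_mean,
                                          fill = .data$condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$accuracy_lo,
                                          ymax = .data$accuracy_hi),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.2) +
      ggplot2::labs(x = "duplication factor", y = "classification accuracy")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(factor(.data$duplication),
                                          .data$util_std_mean,
                                          fill = .data$condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "duplication factor",
                    y = "utilization std (% units)")
  }
  p + ggplot2::facet_grid(.data$layer ~ .data$dataset) +
    ggplot2::theme_minimal()
}
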