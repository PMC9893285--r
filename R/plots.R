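#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PQ-density threshold tuning
#'
#' Sensitivity, specificity and accuracy against the candidate threshold,
#' with the selected balanced threshold marked.
#'
#' @param object A `pq_tuning` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pq_tuning <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$grid, c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      title = paste0("PQ-density threshold tuning (window ", object$window_size, ")"),
      subtitle = paste0("balanced threshold ", format(object$threshold),
                        ", AUROC ", sprintf("%.3f", object$auroc)),
      x = "score threshold", y = "percent", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PQ-density window-size sweep
#'
#' @param object A `pq_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot of sensitivity, specificity and accuracy by window size.
#' @exportS3Method ggplot2::autoplot
autoplot.pq_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$window_size, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window size", y = "percent", colour = NULL,
                  title = "PQ-density performance by window size") +
    ggplot2::theme_minimal()
}

#' Plot a motif coverage table
#'
#' Per-motif coverage bars with the cumulative coverage overlaid.
#'
#' @param object A `coverage_table` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_table <- function(object, ...) {
  d <- as_tibble(object)
  d$motif <- factor(d$motif, levels = d$motif)
  ggplot2::ggplot(d, ggplot2::aes(.data$motif)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$percentage), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::labs(x = NULL, y = "% of positives",
                  title = "Motif coverage of positive peptides",
                  subtitle = "bars: first-match attribution; line: cumulative") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a protein scan
#'
#' Window score along the protein, with positive calls highlighted.
#'
#' @param object A `protein_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.protein_scan <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$start, .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1) +
    ggplot2::labs(x = "window start (1-based)", y = "score",
                  colour = NULL,
                  title = paste0("Scan of ", d$protein_id[1])) +
    ggplot2::theme_minimal()
}
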