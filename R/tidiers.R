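#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PQ-density threshold tuning
#'
#' @param x A `pq_tuning` object.
#' @param ... Unused.
#' @return The threshold grid: one row per candidate threshold with
#'   sensitivity, specificity and accuracy (percentages).
#' @exportS3Method generics::tidy
tidy.pq_tuning <- function(x, ...) {
  x$grid
}

#' @rdname tidy.pq_tuning
#' @return `glance()` returns the selected operating point as a one-row
#'   tibble (window_size, threshold, sensitivity, specificity, accuracy,
#'   auroc, n_positive, n_negative).
#' @exportS3Method generics::glance
glance.pq_tuning <- function(x, ...) {
  tibble(
    window_size = x$window_size,
    threshold = x$threshold,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    accuracy = x$accuracy,
    auroc = x$auroc,
    n_positive = x$n_positive,
    n_negative = x$n_negative
  )
}

#' Tidy a trained composition classifier
#'
#' @param x A `peptide_model`.
#' @param ... Unused.
#' @return Per-fold cross-validation metrics, one row per fold.
#' @exportS3Method generics::tidy
tidy.peptide_model <- function(x, ...) {
  x$cv_metrics
}

#' @rdname tidy.peptide_model
#' @return `glance()` returns a one-row tibble of hold-out validation
#'   metrics plus the classifier kind and threshold.
#' @exportS3Method generics::glance
glance.peptide_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(kind = x$kind, threshold = x$threshold),
    x$validation_metrics,
    tibble(
      n_train = length(x$split$train_ids),
      n_validation = length(x$split$validation_ids)
    )
  )
}
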