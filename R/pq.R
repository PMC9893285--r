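#' Per-window P/Q density profile of a peptide
#'
#' Slides a window of `window_size` residues along the sequence in steps of
#' one and computes, for each window, the fraction of residues that are
#' proline (P) or glutamine (Q). Gluten-derived immunogenic peptides are
#' strongly P/Q-enriched, so the maximum window fraction is a simple and
#' surprisingly strong classifier score.
#'
#' @param sequence A single peptide sequence.
#' @param window_size Window length in residues; must not exceed the peptide
#'   length. The tuned classifiers use 3-9.
#' @return A tibble with one row per window: `start`, `end` (1-based,
#'   inclusive), `window` (the subsequence) and `score` (P+Q fraction in
#'   [0, 1]). There are `L - window_size + 1` rows, in N-to-C order.
#' @examples
#' pq_profile("AAAAQPQPQ", 5) # scores 0.2, 0.4, 0.6, 0.8, 1.0
#' @export
pq_profile <- function(sequence, window_size) {
  stopifnot(length(sequence) == 1L, length(window_size) == 1L)
  sequence <- toupper(sequence)
  validate_sequences(sequence, "query")
  window_size <- as.integer(window_size)
  L <- nchar(sequence)
  if (window_size < 1L) abort("`window_size` must be >= 1.")
  if (window_size > L) {
    abort(paste0(
      "`window_size` (", window_size, ") exceeds peptide length (", L,
      "); use a shorter window or skip this peptide."
    ))
  }
  is_pq <- strsplit(sequence, "")[[1L]] %in% c("P", "Q")
  # windowed counts from the running sum: count_i = cs[i+w] - cs[i]
  cs <- c(0, cumsum(is_pq))
  starts <- seq_len(L - window_size + 1L)
  counts <- cs[starts + window_size] - cs[starts]
  tibble(
    start = starts,
    end = starts + window_size - 1L,
    window = substring(sequence, starts, starts + window_size - 1L),
    score = counts / window_size
  )
}

#' Maximum P/Q window density (the PQ-density score)
#'
#' The PQ-density score of a peptide is the maximum, over all overlapping
#' windows of `window_size` residues, of the within-window P+Q fraction.
#' Vectorised over sequences.
#'
#' @param sequence Character vector of peptide sequences.
#' @inheritParams pq_profile
#' @return Numeric vector of scores in [0, 1].
#' @examples
#' pq_score(c("AAAAQPQPQ", "QAPAQAPAQ"), c(5, 3))
#' @export
pq_score <- function(sequence, window_size) {
  sequence <- toupper(as.character(sequence))
  validate_sequences(sequence, if (is.null(names(sequence))) paste0("query", seq_along(sequence)) else names(sequence))
  n <- max(length(sequence), length(window_size))
  sequence <- rep_len(sequence, n)
  window_size <- rep_len(as.integer(window_size), n)
  vapply(seq_len(n), function(i) {
    w <- window_size[i]
    L <- nchar(sequence[i])
    if (w < 1L) abort("`window_size` must be >= 1.")
    if (w > L) {
      abort(paste0(
        "`window_size` (", w, ") exceeds peptide length (", L,
        "); use a shorter window or skip this peptide."
      ))
    }
    is_pq <- strsplit(sequence[i], "")[[1L]] %in% c("P", "Q")
    cs <- c(0, cumsum(is_pq))
    starts <- seq_len(L - w + 1L)
    max(cs[starts + w] - cs[starts]) / w
  }, numeric(1))
}

#' Classify peptides by PQ-density threshold
#'
#' A peptide is called positive when its PQ-density score is greater than or
#' equal to `threshold` (the boundary counts as positive).
#'
#' @inheritParams pq_score
#' @param threshold Score threshold in [0, 1].
#' @return Character vector of `"positive"` / `"negative"` labels.
#' @export
classify_pq <- function(sequence, window_size, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(pq_score(sequence, window_size) >= threshold, "positive", "negative")
}

#' A PQ-density predictor object
#'
#' Packages a window size and threshold into a predictor usable wherever a
#' trained model is accepted (protein scanning, analog design, the CLI's
#' `pqdensity` mode). Its score is the raw PQ density.
#'
#' @param window_size Window length (default 5, the best-performing size on
#'   balanced data).
#' @param threshold Positive-call threshold on the score (default 0.41, the
#'   balanced operating point for window 5 on the reference balanced data).
#' @return An object of class `pq_classifier`.
#' @examples
#' peptide_scores(pq_classifier(), peptide_tbl("QPQLPYPQPQ"))
#' @export
pq_classifier <- function(window_size = 5L, threshold = 0.41) {
  stopifnot(window_size >= 1L, threshold >= 0, threshold <= 1)
  structure(
    list(window_size = as.integer(window_size), threshold = threshold),
    class = "pq_classifier"
  )
}

#' @export
print.pq_classifier <- function(x, ...) {
  cat("PQ-density classifier: window", x$window_size,
      "| threshold", format(x$threshold), "\n")
  invisible(x)
}

#' Tune a balanced PQ-density threshold
#'
#' Evaluates every threshold on a regular grid (0, `grid_step`, ..., 1)
#' against the PQ-density scores of a labeled dataset, computing
#' sensitivity, specificity and accuracy at each, and selects the balanced
#' operating point: minimal |sensitivity - specificity|, ties broken by
#' higher accuracy, then by the smaller threshold. The threshold-independent
#' AUROC of the raw scores is reported alongside.
#'
#' @param data Labeled peptide data frame; every peptide must be at least
#'   `window_size` long.
#' @param window_size Window length for [pq_score()].
#' @param grid_step Threshold grid spacing (default 0.01).
#' @return An object of class `pq_tuning` with fields `window_size`,
#'   `grid` (tibble: threshold, sensitivity, specificity, accuracy),
#'   `threshold` (the selected balanced threshold), `auroc`, `n_positive`,
#'   `n_negative`. Supports [generics::tidy()], [generics::glance()] and
#'   `autoplot()`.
#' @export
tune_pq_threshold <- function(data, window_size, grid_step = 0.01) {
  check_peptide_df(data, need_label = TRUE)
  if (length(unique(data$label)) < 2L) {
    abort("Threshold tuning needs both positive and negative peptides.")
  }
  scores <- pq_score(data$sequence, window_size)
  truth <- as.integer(data$label == "positive")
  grid_t <- seq(0L, round(1 / grid_step)) * grid_step
  grid <- purrr::map_dfr(grid_t, function(t) {
    cc <- confusion_counts(truth, as.integer(scores >= t))
    m <- classification_metrics(cc)
    tibble(
      threshold = t,
      sensitivity = m$sensitivity,
      specificity = m$specificity,
      accuracy = m$accuracy
    )
  })
  balance <- abs(grid$sensitivity - grid$specificity)
  best <- order(balance, -grid$accuracy, grid$threshold)[1L]
  structure(
    list(
      window_size = as.integer(window_size),
      grid = grid,
      threshold = grid$threshold[best],
      sensitivity = grid$sensitivity[best],
      specificity = grid$specificity[best],
      accuracy = grid$accuracy[best],
      auroc = auroc(truth, scores),
      n_positive = sum(truth == 1L),
      n_negative = sum(truth == 0L)
    ),
    class = "pq_tuning"
  )
}

#' @export
print.pq_tuning <- function(x, ...) {
  cat("PQ-density threshold tuning (window ", x$window_size, ")\n", sep = "")
  cat(sprintf(
    "  threshold %.2f | Sens %.2f%% | Spec %.2f%% | Acc %.2f%% | AUROC %.3f\n",
    x$threshold, x$sensitivity, x$specificity, x$accuracy, x$auroc
  ))
  cat("  tuned on", x$n_positive, "positives /", x$n_negative, "negatives\n")
  invisible(x)
}

#' PQ-density performance across window sizes
#'
#' Runs [tune_pq_threshold()] for each window size and assembles one row per
#' size (threshold, sensitivity, specificity, accuracy, AUROC). Peptides
#' shorter than a given window are excluded from that window's evaluation;
#' the number skipped is recorded in the `n_skipped` column and reported via
#' a message.
#'
#' @param data Labeled peptide data frame.
#' @param window_sizes Integer vector of window lengths (default 3:9).
#' @param grid_step Threshold grid spacing passed through.
#' @return A tibble of class `pq_sweep` with columns `window_size`,
#'   `threshold`, `sensitivity`, `specificity`, `accuracy`, `auroc`,
#'   `n_used`, `n_skipped`.
#' @export
pq_window_sweep <- function(data, window_sizes = 3:9, grid_step = 0.01) {
  check_peptide_df(data, need_label = TRUE)
  rows <- purrr::map_dfr(as.integer(window_sizes), function(w) {
    keep <- nchar(data$sequence) >= w
    if (any(!keep)) {
      message(sum(!keep), " peptide(s) shorter than window ", w, " skipped.")
    }
    fit <- tune_pq_threshold(data[keep, , drop = FALSE], w, grid_step)
    tibble(
      window_size = w,
      threshold = fit$threshold,
      sensitivity = fit$sensitivity,
      specificity = fit$specificity,
      accuracy = fit$accuracy,
      auroc = fit$auroc,
      n_used = sum(keep),
      n_skipped = sum(!keep)
    )
  })
  class(rows) <- c("pq_sweep", class(rows))
  rows
}
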