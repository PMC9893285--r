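#' Confusion-matrix counts
#'
#' @param truth Vector of true labels (1/0, TRUE/FALSE or
#'   positive/negative).
#' @param predicted Vector of predicted labels, same encodings.
#' @return A one-row tibble with integer columns `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 1, 0), c(1, 0, 1, 0))
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as_binary(truth)
  predicted <- as_binary(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length.")
  }
  if (length(truth) == 0L) abort("Need at least one item.")
  tibble(
    tp = sum(truth == 1L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fp = sum(truth == 0L & predicted == 1L),
    fn = sum(truth == 1L & predicted == 0L)
  )
}

as_binary <- function(x) {
  if (is.character(x) || is.factor(x)) {
    as.integer(normalize_labels(as.character(x)) == "positive")
  } else {
    xi <- as.integer(x)
    if (anyNA(xi) || any(!xi %in% c(0L, 1L))) {
      abort("Labels must be 0/1, TRUE/FALSE or positive/negative.")
    }
    xi
  }
}

#' Threshold-dependent classification metrics
#'
#' Computes the standard confusion-matrix summaries: sensitivity
#' `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, accuracy
#' `100*(TP+TN)/total` (all percentages), F1 `2TP/(2TP+FP+FN)` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (fractions). When
#' an MCC marginal is zero the coefficient is reported as 0 by convention;
#' sensitivity (specificity) is 0 when no positives (negatives) exist.
#'
#' @param counts A one-row data frame with columns `tp`, `tn`, `fp`, `fn`
#'   (see [confusion_counts()]), or four counts given separately.
#' @param tn,fp,fn Individual counts when `counts` is the TP count.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`
#'   (percentages), `f1`, `mcc`.
#' @examples
#' classification_metrics(30, 40, 10, 20) # Sens 60, Spec 80, Acc 70
#' @export
classification_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (is.data.frame(counts)) {
    tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
    fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  } else {
    tp <- as.numeric(counts); tn <- as.numeric(tn)
    fp <- as.numeric(fp); fn <- as.numeric(fn)
  }
  total <- tp + tn + fp + fn
  if (total <= 0) abort("Confusion counts sum to zero.")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble(
    sensitivity = 100 * safe_div(tp, tp + fn),
    specificity = 100 * safe_div(tn, tn + fp),
    accuracy = 100 * (tp + tn) / total,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  )
}

#' Area under the ROC curve (rank-sum formulation)
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half -- the
#' Mann-Whitney U statistic normalised by the number of positive-negative
#' pairs. Identical to trapezoidal integration of the ROC curve.
#'
#' @param truth True labels (1/0 or positive/negative); both classes must be
#'   present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)) # 0.75
#' @export
auroc <- function(truth, scores) {
  truth <- as_binary(truth)
  if (length(truth) != length(scores)) {
    abort("`truth` and `scores` must have the same length.")
  }
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUROC needs both classes present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified 80:20 split with five cross-validation folds
#'
#' Shuffles each label class with the given seed, reserves ~20% of each
#' class (rounded to nearest) as the external validation set, and partitions
#' the remaining 80% into five stratified folds whose per-class sizes differ
#' by at most one. This is the evaluation protocol used by
#' [train_peptide_model()]: models are tuned by five-fold cross-validation
#' on the training portion and assessed once on the untouched validation
#' portion.
#'
#' @param data Labeled peptide data frame with at least 5 records per class.
#' @param seed Integer seed controlling the shuffle; the same seed always
#'   yields the same plan.
#' @param validation_fraction Fraction held out per class (default 0.2).
#' @param n_folds Number of folds over the training portion (default 5).
#' @return A list of class `split_plan`: `train_ids`, `validation_ids`
#'   (disjoint character vectors) and `folds` (list of `n_folds` id vectors
#'   partitioning `train_ids`), plus the seed.
#' @export
make_split <- function(data, seed, validation_fraction = 0.2, n_folds = 5L) {
  check_peptide_df(data, need_label = TRUE)
  counts <- table(data$label)
  if (length(counts) < 2L || any(counts < n_folds)) {
    abort(paste0("Need at least ", n_folds, " records in each class."))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  val <- character()
  folds <- vector("list", n_folds)
  for (cls in sort(unique(data$label))) {
    ids <- sample(data$id[data$label == cls])
    n_val <- round(validation_fraction * length(ids))
    val <- c(val, ids[seq_len(n_val)])
    tr <- ids[-seq_len(n_val)]
    assignment <- rep_len(seq_len(n_folds), length(tr))
    for (k in seq_len(n_folds)) folds[[k]] <- c(folds[[k]], tr[assignment == k])
  }
  structure(
    list(
      train_ids = sort(setdiff(data$id, val)),
      validation_ids = sort(val),
      folds = lapply(folds, sort),
      seed = as.integer(seed)
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Stratified split (seed ", x$seed, "): ",
      length(x$train_ids), " train / ", length(x$validation_ids),
      " validation; ", length(x$folds), " folds of sizes ",
      paste(lengths(x$folds), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
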