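#' Supported classifier kinds
#'
#' The amino-acid-composition classifier panel: decision tree (`dt`), random
#' forest (`rf`), logistic regression (`lr`), gradient-boosted trees
#' (`xgb`), k-nearest neighbours (`knn`), Gaussian naive Bayes (`gnb`),
#' extremely randomised trees (`et`, the default deployed kind) and a
#' support-vector classifier (`svc`).
#'
#' @return Character vector of kind codes.
#' @export
classifier_kinds <- function() {
  c("dt", "rf", "lr", "xgb", "knn", "gnb", "et", "svc")
}

default_hyperparameters <- function(kind) {
  switch(kind,
    dt = list(),
    rf = list(num.trees = 500L),
    lr = list(),
    xgb = list(nrounds = 100L, max_depth = 4L, eta = 0.3),
    knn = list(k = 5L),
    gnb = list(laplace = 0),
    et = list(num.trees = 500L),
    svc = list(kernel = "radial", cost = 1)
  )
}

#' Train a composition classifier under the hold-out + cross-validation protocol
#'
#' Featurizes the labeled peptides as 20-column amino-acid composition rows,
#' builds a stratified 80:20 split with five folds over the training portion
#' ([make_split()]), estimates training performance as the unweighted mean
#' of the five per-fold metric rows, refits on the full 80%, and evaluates
#' once on the untouched 20% validation set. All metrics use the model's
#' score threshold (default 0.5) for the threshold-dependent quantities,
#' plus AUROC of the raw scores.
#'
#' Training is deterministic given (`data`, `kind`, `seed`).
#'
#' @param data Labeled peptide data frame, at least 10 records per class.
#' @param kind Classifier kind, see [classifier_kinds()]; default `"et"`.
#' @param seed Integer seed controlling the split and any stochastic
#'   fitting.
#' @param threshold Score threshold for positive calls (default 0.5).
#' @param hyperparameters Named list overriding the kind's defaults.
#' @return An object of class `peptide_model` with the fitted classifier,
#'   `cv_metrics` (per-fold tibble), `train_metrics` (their mean),
#'   `validation_metrics`, and the split. Supports `predict()`,
#'   [peptide_scores()], [generics::tidy()] and [generics::glance()].
#' @examples
#' \donttest{
#' d <- simulate_peptides(n_positive = 60, n_negative = 60, seed = 1)
#' fit <- train_peptide_model(d, kind = "lr", seed = 1)
#' glance(fit)
#' }
#' @export
train_peptide_model <- function(data, kind = "et", seed = 1L, threshold = 0.5,
                                hyperparameters = list()) {
  check_peptide_df(data, need_label = TRUE)
  kind <- tolower(kind)
  if (!kind %in% classifier_kinds()) {
    abort(paste0(
      "Unknown classifier kind '", kind, "'. Valid kinds: ",
      paste(classifier_kinds(), collapse = ", "), "."
    ))
  }
  counts <- table(data$label)
  if (length(counts) < 2L || any(counts < 10L)) {
    abort("Training needs at least 10 records in each of the two classes.")
  }
  hyper <- modifyList(default_hyperparameters(kind), hyperparameters)
  feats <- aac_features(data)
  X <- as.matrix(feats[, AA_ALPHABET])
  rownames(X) <- feats$id
  y <- setNames(as.integer(data$label == "positive"), data$id)

  plan <- make_split(data, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  cv <- purrr::map_dfr(seq_along(plan$folds), function(k) {
    held <- plan$folds[[k]]
    tr <- setdiff(plan$train_ids, held)
    fit_k <- fit_classifier(kind, X[tr, , drop = FALSE], y[tr], hyper,
                            seed = as.integer(seed) + k)
    s <- score_classifier(fit_k, X[held, , drop = FALSE])
    m <- classification_metrics(confusion_counts(y[held], as.integer(s >= threshold)))
    m$auroc <- auroc(y[held], s)
    m$fold <- k
    m
  })
  train_metrics <- dplyr::summarise(
    cv,
    dplyr::across(c("sensitivity", "specificity", "accuracy", "f1", "mcc", "auroc"), mean)
  )

  fit <- fit_classifier(kind, X[plan$train_ids, , drop = FALSE],
                        y[plan$train_ids], hyper, seed = as.integer(seed))
  val_scores <- score_classifier(fit, X[plan$validation_ids, , drop = FALSE])
  val_truth <- y[plan$validation_ids]
  validation_metrics <- classification_metrics(
    confusion_counts(val_truth, as.integer(val_scores >= threshold))
  )
  validation_metrics$auroc <- auroc(val_truth, val_scores)

  structure(
    list(
      kind = kind,
      hyperparameters = hyper,
      fit = fit,
      threshold = threshold,
      feature_spec = "AAC-20, alphabetical",
      seed = as.integer(seed),
      split = plan,
      cv_metrics = dplyr::relocate(cv, "fold"),
      train_metrics = train_metrics,
      validation_metrics = validation_metrics
    ),
    class = "peptide_model"
  )
}

# ---- classifier backends ---------------------------------------------------

fit_classifier <- function(kind, X, y, hyper, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(0L, 1L))
  df <- as.data.frame(X)
  fit <- switch(kind,
    dt = rpart::rpart(.y ~ ., data = cbind(df, .y = yf), method = "class"),
    rf = ranger::ranger(
      x = df, y = yf, probability = TRUE,
      num.trees = hyper$num.trees, seed = seed, num.threads = 1L
    ),
    et = ranger::ranger(
      x = df, y = yf, probability = TRUE,
      num.trees = hyper$num.trees, splitrule = "extratrees",
      replace = FALSE, sample.fraction = 1,
      seed = seed, num.threads = 1L
    ),
    lr = suppressWarnings(
      glm(.y ~ ., data = cbind(df, .y = yf), family = binomial())
    ),
    xgb = xgboost::xgboost(
      x = X, y = yf, nrounds = hyper$nrounds,
      max_depth = hyper$max_depth, learning_rate = hyper$eta,
      nthreads = 1L, verbosity = 0
    ),
    knn = list(train = X, y = yf, k = hyper$k),
    gnb = e1071::naiveBayes(x = df, y = yf, laplace = hyper$laplace),
    svc = e1071::svm(
      x = X, y = yf, probability = TRUE,
      kernel = hyper$kernel, cost = hyper$cost
    )
  )
  structure(list(kind = kind, object = fit, seed = seed),
            class = "celiacpep_fit")
}

# positive-class score in [0, 1] for each row of X
score_classifier <- function(fit, X) {
  df <- as.data.frame(X)
  obj <- fit$object
  s <- switch(fit$kind,
    dt = predict(obj, newdata = df, type = "prob")[, "1"],
    rf = predict(obj, data = df, num.threads = 1L)$predictions[, "1"],
    et = predict(obj, data = df, num.threads = 1L)$predictions[, "1"],
    lr = suppressWarnings(
      predict(obj, newdata = df, type = "response")
    ),
    xgb = predict(obj, X, type = "response"),
    knn = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(fit$seed) # class::knn breaks exact distance ties at random
      pred <- class::knn(obj$train, X, obj$y, k = obj$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    gnb = predict(obj, newdata = df, type = "raw", threshold = 1e-3)[, "1"],
    svc = attr(
      predict(obj, X, probability = TRUE), "probabilities"
    )[, "1"]
  )
  unname(pmin(pmax(as.numeric(s), 0), 1))
}

# ---- user-facing prediction -------------------------------------------------

#' Score peptides with a fitted predictor
#'
#' Generic scoring interface shared by composition classifiers
#' ([train_peptide_model()]), the PQ-density predictor ([pq_classifier()])
#' and the motif-first ensemble ([ensemble_model()]), so that protein
#' scanning and analog design work with any of them.
#'
#' @param object A fitted predictor.
#' @param data Peptide data frame (or character vector of sequences).
#' @param ... Passed to methods.
#' @return A tibble with columns `id`, `score` (in [0, 1]) and `label`;
#'   ensemble predictions add `provenance` and `matched_motif`.
#' @export
peptide_scores <- function(object, data, ...) {
  UseMethod("peptide_scores")
}

#' @export
peptide_scores.peptide_model <- function(object, data, ...) {
  if (is.character(data)) data <- peptide_tbl(data)
  check_peptide_df(data)
  if (is.null(object$fit)) abort("Model is not fitted.")
  feats <- aac_features(data)
  s <- score_classifier(object$fit, as.matrix(feats[, AA_ALPHABET]))
  tibble(
    id = data$id,
    score = s,
    label = ifelse(s >= object$threshold, "positive", "negative")
  )
}

#' @export
peptide_scores.pq_classifier <- function(object, data, ...) {
  if (is.character(data)) data <- peptide_tbl(data)
  check_peptide_df(data)
  s <- pq_score(data$sequence, object$window_size)
  tibble(
    id = data$id,
    score = s,
    label = ifelse(s >= object$threshold, "positive", "negative")
  )
}

#' @rdname peptide_scores
#' @param newdata Peptide data frame to score.
#' @export
predict.peptide_model <- function(object, newdata, ...) {
  peptide_scores(object, newdata, ...)
}

#' @export
print.peptide_model <- function(x, ...) {
  cat("Composition classifier (", toupper(x$kind), ", AAC-20 features)\n", sep = "")
  v <- x$validation_metrics
  cat(sprintf(
    "  validation: Sens %.2f%% | Spec %.2f%% | Acc %.2f%% | AUROC %.3f | MCC %.3f\n",
    v$sensitivity, v$specificity, v$accuracy, v$auroc, v$mcc
  ))
  cat("  threshold ", format(x$threshold), ", seed ", x$seed, ", ",
      length(x$split$train_ids), " train / ",
      length(x$split$validation_ids), " validation peptides\n", sep = "")
  invisible(x)
}

# ---- persistence -----------------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted predictor
#'
#' Models are stored as a single-file bundle recording a format version, the
#' classifier kind, hyperparameters, feature specification and score
#' threshold. Loading verifies the format and version and reproduces
#' predictions exactly.
#'
#' @param model A `peptide_model` or `ensemble_model`.
#' @param path File path for the bundle.
#' @return `save_peptide_model()` returns `path` invisibly;
#'   `load_peptide_model()` returns the model.
#' @export
save_peptide_model <- function(model, path) {
  if (!inherits(model, c("peptide_model", "ensemble_model"))) {
    abort("`model` must be a peptide_model or ensemble_model.")
  }
  saveRDS(
    list(
      format = "celiacpep_model_bundle",
      version = MODEL_FORMAT_VERSION,
      model = model
    ),
    path
  )
  invisible(path)
}

#' @rdname save_peptide_model
#' @param path File path of a saved bundle.
#' @export
load_peptide_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  bundle <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Not a readable model bundle: ", path, " (", conditionMessage(e), ")"))
  })
  if (!is.list(bundle) || !identical(bundle$format, "celiacpep_model_bundle")) {
    abort(paste0("File ", path, " is not a celiacpep model bundle."))
  }
  if (!identical(bundle$version, MODEL_FORMAT_VERSION)) {
    abort(paste0(
      "Model bundle version ", bundle$version,
      " is not supported by this build (expected ", MODEL_FORMAT_VERSION, ")."
    ))
  }
  bundle$model
}
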