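#' Motif-first ensemble predictor
#'
#' Combines an ordered motif set with a trained composition classifier. The
#' decision rule has strict motif precedence: a peptide containing any motif
#' of the set is called positive with provenance `"motif"`, irrespective of
#' its classifier score; only motif-free peptides are decided by the
#' classifier (provenance `"ML"`). Motifs can therefore only assert
#' positives, never veto them.
#'
#' @param motifs Ordered motif patterns (character vector, `motif_set`, or
#'   data frame with a `pattern` column); the order is the first-match
#'   attribution order used in coverage reports. Defaults to the shipped
#'   [celiac_motifs()] set.
#' @param model A fitted `peptide_model`.
#' @param ml_threshold Score threshold for the classifier path (default
#'   0.5).
#' @return An object of class `ensemble_model`.
#' @export
ensemble_model <- function(motifs = celiac_motifs(), model, ml_threshold = 0.5) {
  patterns <- motif_patterns(motifs)
  if (length(patterns) == 0L) abort("The ensemble motif set must be non-empty.")
  if (!inherits(model, "peptide_model")) {
    abort("`model` must be a fitted peptide_model.")
  }
  stopifnot(ml_threshold >= 0, ml_threshold <= 1)
  structure(
    list(motifs = patterns, model = model, ml_threshold = ml_threshold),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Motif-first ensemble:", length(x$motifs), "motifs (",
      paste(head(x$motifs, 5), collapse = ", "),
      if (length(x$motifs) > 5) ", ..." else "", ") + ",
      toupper(x$model$kind), " classifier @ threshold ",
      format(x$ml_threshold), "\n", sep = "")
  invisible(x)
}

#' Predict with the motif-first ensemble
#'
#' @param model An [ensemble_model()].
#' @param data Peptide data frame or character vector of sequences.
#' @return A tibble with one row per peptide: `id`, `label`, `provenance`
#'   (`"motif"` or `"ML"`), `matched_motif` (the first matching motif in set
#'   order, `NA` on the ML path) and `ml_score` (`NA` on the motif path).
#' @examples
#' \donttest{
#' d <- simulate_peptides(n_positive = 60, n_negative = 60, seed = 1)
#' fit <- train_peptide_model(d, kind = "lr", seed = 1)
#' ens <- ensemble_model(model = fit)
#' predict_ensemble(ens, peptide_tbl(c("LQLQPFAAA", "AAAAAAAAA")))
#' }
#' @export
predict_ensemble <- function(model, data) {
  if (!inherits(model, "ensemble_model")) {
    abort("`model` must be an ensemble_model.")
  }
  if (is.character(data)) data <- peptide_tbl(data)
  check_peptide_df(data)
  matched <- rep(NA_character_, nrow(data))
  for (m in model$motifs) {
    free <- is.na(matched)
    if (!any(free)) break
    hit <- free & stringr::str_detect(data$sequence, stringr::fixed(m))
    matched[hit] <- m
  }
  out <- tibble(
    id = data$id,
    label = NA_character_,
    provenance = ifelse(is.na(matched), "ML", "motif"),
    matched_motif = matched,
    ml_score = NA_real_
  )
  out$label[!is.na(matched)] <- "positive"
  todo <- is.na(matched)
  if (any(todo)) {
    ml <- peptide_scores(model$model, data[todo, , drop = FALSE])
    out$ml_score[todo] <- ml$score
    out$label[todo] <- ifelse(ml$score >= model$ml_threshold,
                              "positive", "negative")
  }
  out
}

#' @export
peptide_scores.ensemble_model <- function(object, data, ...) {
  pred <- predict_ensemble(object, data)
  # motif hits are certain positives on the ensemble's score scale
  tibble(
    id = pred$id,
    score = ifelse(pred$provenance == "motif", 1, pred$ml_score),
    label = pred$label,
    provenance = pred$provenance,
    matched_motif = pred$matched_motif
  )
}

#' Motif-coverage report for an ensemble
#'
#' Delegates to [motif_coverage()] with the ensemble's stored motif order;
#' the residual row counts the positives the classifier path would handle.
#'
#' @param model An [ensemble_model()].
#' @param positives Peptide data frame of positive sequences.
#' @return A `coverage_table` tibble.
#' @export
ensemble_coverage <- function(model, positives) {
  if (!inherits(model, "ensemble_model")) {
    abort("`model` must be an ensemble_model.")
  }
  motif_coverage(model$motifs, positives)
}
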