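#' Build a validated peptide table
#'
#' The central data structure of the package is a plain tibble with columns
#' `id` (character, non-empty, unique), `sequence` (uppercase strings over the
#' 20 standard one-letter amino-acid codes) and, optionally, `label`
#' (`"positive"` / `"negative"`). `peptide_tbl()` normalises and validates
#' input and is called by all readers; analysis functions accept any data
#' frame with these columns.
#'
#' @param sequence Character vector of amino-acid sequences (case-insensitive).
#' @param id Optional character vector of identifiers; defaults to
#'   `pep1 ... pepN`. Duplicate ids are disambiguated with a numeric suffix.
#' @param label Optional labels; accepted encodings are `"positive"`/
#'   `"negative"`, `1`/`0`, `TRUE`/`FALSE`.
#'
#' @return A tibble with columns `id`, `sequence` and (if labels were given)
#'   `label`.
#' @examples
#' peptide_tbl(c("QPQLPYPQPQ", "acdefghik"), label = c(1, 0))
#' @export
peptide_tbl <- function(sequence, id = NULL, label = NULL) {
  if (length(sequence) == 0L) {
    out <- tibble(id = character(), sequence = character())
    if (!is.null(label)) out$label <- character()
    return(out)
  }
  sequence <- toupper(as.character(sequence))
  if (is.null(id)) id <- paste0("pep", seq_along(sequence))
  id <- as.character(id)
  if (length(id) != length(sequence)) {
    abort("`id` and `sequence` must have the same length.")
  }
  if (any(!nzchar(id)) || anyNA(id)) abort("Peptide ids must be non-empty.")
  id <- make_unique_ids(id)
  validate_sequences(sequence, id)
  out <- tibble(id = id, sequence = sequence)
  if (!is.null(label)) out$label <- normalize_labels(label)
  out
}

# Disambiguate duplicate ids with a numeric suffix (first keeps the bare name).
make_unique_ids <- function(id) {
  if (!anyDuplicated(id)) return(id)
  ave(id, id, FUN = function(x) {
    if (length(x) == 1L) x else c(x[1L], paste0(x[-1L], "_", seq_len(length(x) - 1L) + 1L))
  })
}

normalize_labels <- function(label) {
  if (is.logical(label)) label <- ifelse(label, "positive", "negative")
  label <- as.character(label)
  map <- c(
    "1" = "positive", "0" = "negative",
    "positive" = "positive", "negative" = "negative",
    "pos" = "positive", "neg" = "negative"
  )
  out <- unname(map[tolower(label)])
  if (anyNA(out)) {
    bad <- unique(label[is.na(out)])
    abort(paste0(
      "Unrecognised label value(s): ", paste(bad, collapse = ", "),
      ". Use positive/negative, 1/0 or TRUE/FALSE."
    ))
  }
  out
}

# Reject any character outside the 20-letter alphabet, naming record and
# offender; composition and PQ-density statistics are only defined over the
# standard alphabet.
validate_sequences <- function(sequence, id) {
  if (any(!nzchar(sequence))) {
    abort(paste0("Empty sequence for record(s): ",
                 paste(id[!nzchar(sequence)], collapse = ", ")))
  }
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- setdiff(strsplit(sequence[i], "")[[1L]], AA_ALPHABET)
    abort(paste0(
      "Record '", id[i], "' contains invalid residue character(s): ",
      paste(unique(ch), collapse = ", "),
      ". Only the 20 standard amino-acid codes are allowed."
    ))
  }
  invisible(sequence)
}

check_peptide_df <- function(data, need_label = FALSE) {
  if (!is.data.frame(data) || !all(c("id", "sequence") %in% names(data))) {
    abort("Expected a peptide data frame with columns `id` and `sequence`.")
  }
  if (need_label && !"label" %in% names(data)) {
    abort("This operation needs a `label` column (positive/negative).")
  }
  invisible(data)
}

#' Filter peptides by length and deduplicate within label class
#'
#' Applies the dataset construction rule used throughout the package: keep
#' peptides whose length lies in `[min_len, max_len]` (defaults 9-20, the
#' range of experimentally catalogued CD epitopes) and drop duplicate
#' sequences within each label class, keeping the first occurrence.
#'
#' @param data Peptide data frame (see [peptide_tbl()]).
#' @param min_len,max_len Inclusive length bounds.
#' @return A tibble with the retained rows, in input order.
#' @examples
#' d <- peptide_tbl(c("ACDEFGHI", "ACDEFGHIK", "ACDEFGHIK"), label = c(1, 1, 1))
#' filter_peptides(d) # 8-mer dropped, duplicate 9-mer kept once
#' @export
filter_peptides <- function(data, min_len = 9L, max_len = 20L) {
  check_peptide_df(data)
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")
  out <- dplyr::filter(
    as_tibble(data),
    nchar(.data$sequence) >= min_len,
    nchar(.data$sequence) <= max_len
  )
  if ("label" %in% names(out)) {
    out <- dplyr::distinct(out, .data$label, .data$sequence, .keep_all = TRUE)
  } else {
    out <- dplyr::distinct(out, .data$sequence, .keep_all = TRUE)
  }
  dplyr::relocate(out, "id", "sequence")
}

#' Fixed-length 18-mer termini vector
#'
#' Concatenates the first nine and last nine residues of a peptide into a
#' fixed 18-residue string. This is the standard device for aligning
#' variable-length (9-20 aa) peptides into a fixed frame: the N-terminal
#' 9-mer occupies positions 1-9 and the C-terminal 9-mer positions 10-18.
#' For a 9-mer the two halves coincide; for an 18-mer the vector is the
#' sequence itself.
#'
#' @param sequence Character vector of peptide sequences, each of length >= 9.
#' @return Character vector of 18-residue strings.
#' @examples
#' termini_vector("ACDEFGHIKLMN")
#' @export
termini_vector <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (any(L < 9L)) {
    abort(paste0(
      "termini_vector() needs sequences of length >= 9; got length ",
      min(L), "."
    ))
  }
  paste0(substr(sequence, 1L, 9L), substr(sequence, L - 8L, L))
}

#' Amino-acid composition of a single sequence
#'
#' The composition of residue type i in a peptide of length L is
#' `100 * (count of i) / L`, giving a 20-vector of percentages that sums to
#' 100. Residues absent from the sequence get 0.
#'
#' @param sequence A single peptide sequence.
#' @return Named numeric vector of 20 percentages, in alphabetical residue
#'   order (A, C, D, ..., Y).
#' @examples
#' aac_composition("QPQLPYPQPQ") # Q 40, P 40, L 10, Y 10
#' @export
aac_composition <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  validate_sequences(sequence, "query")
  counts <- Biostrings::letterFrequency(
    Biostrings::AAString(sequence),
    letters = AA_ALPHABET
  )
  setNames(as.numeric(counts) / nchar(sequence) * 100, AA_ALPHABET)
}

#' Amino-acid composition feature matrix
#'
#' One row per peptide, 20 numeric columns in fixed alphabetical residue
#' order; every row sums to 100. This is the feature representation consumed
#' by [train_peptide_model()].
#'
#' @param data Peptide data frame.
#' @return A tibble with columns `id`, the 20 residue percentages, and
#'   `label` when present in the input; rows in input order.
#' @examples
#' aac_features(peptide_tbl(c("PPPPPPPPPP", "QPQLPYPQPQ")))
#' @export
aac_features <- function(data) {
  check_peptide_df(data)
  validate_sequences(data$sequence, data$id)
  counts <- Biostrings::letterFrequency(
    Biostrings::AAStringSet(data$sequence),
    letters = AA_ALPHABET
  )
  frac <- counts / nchar(data$sequence) * 100
  out <- dplyr::bind_cols(tibble(id = data$id), as_tibble(frac))
  if ("label" %in% names(data)) out$label <- data$label
  out
}
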