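#' Read peptides from a FASTA file
#'
#' Standard multi-line FASTA is accepted. The record id is the header up to
#' the first whitespace; duplicate ids receive a numeric suffix. Sequences
#' are uppercased and validated against the 20-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @param label Optional label applied to every record (`"positive"`,
#'   `"negative"`, 1, 0) -- convenient when positives and negatives live in
#'   separate files.
#' @return A peptide tibble (see [peptide_tbl()]), in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "qpqlpypqpq"), f)
#' read_peptide_fasta(f)
#' @export
read_peptide_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) abort(paste0("Empty FASTA file: ", path))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    abort(paste0(
      "Malformed FASTA in ", path, ": line ", nonblank[1L],
      " contains sequence before any '>' header."
    ))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lab <- if (is.null(label)) NULL else rep(label, length(set))
  peptide_tbl(as.character(set), id = ids, label = lab)
}

#' Write peptides to a FASTA file
#'
#' Emits single-line records. Round-trips ids and sequences exactly with
#' [read_peptide_fasta()].
#'
#' @param data Peptide data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(data, path) {
  check_peptide_df(data)
  set <- Biostrings::BStringSet(setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Read a labeled peptide dataset from TSV
#'
#' Two tab-separated columns: sequence and label (1 = positive, 0 =
#' negative). A header row is auto-detected: if the second field of the
#' first line is not a recognisable label the line is treated as a header.
#'
#' @param path Path to the TSV file.
#' @return A labeled peptide tibble; ids are `pep1 ... pepN` in file order.
#' @export
read_peptide_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1L]]
  has_header <- length(first) >= 2L &&
    !tolower(first[2L]) %in% c("0", "1", "positive", "negative", "pos", "neg")
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("sequence", "label"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (has_header) names(tab)[1:2] <- c("sequence", "label")
  if (ncol(tab) < 2L) abort("TSV must have two columns: sequence, label.")
  peptide_tbl(tab$sequence, label = tab$label)
}

#' Write a labeled peptide dataset to TSV
#'
#' @param data Labeled peptide data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_tsv <- function(data, path) {
  check_peptide_df(data, need_label = TRUE)
  readr::write_tsv(
    tibble(
      sequence = data$sequence,
      label = ifelse(data$label == "positive", 1L, 0L)
    ),
    path, col_names = FALSE
  )
  invisible(path)
}
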