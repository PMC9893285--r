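#' Discover class-exclusive ungapped motifs
#'
#' Enumerates every distinct substring of length `kmin`..`kmax` across the
#' positive set, counts the number of positive and negative *sequences*
#' containing each (a sequence containing a pattern twice counts once), and
#' keeps patterns supported by at least `min_positive` positives and at most
#' `max_negative` negatives. Redundant patterns are then removed: a pattern
#' is redundant when another retained pattern is a proper substring of it
#' (the shorter pattern necessarily covers a superset of its positive
#' sequences). The result is ordered by positive support (descending), ties
#' by pattern.
#'
#' With the defaults (`max_negative = 0`) discovery is strictly
#' class-exclusive: a single negative occurrence disqualifies a pattern.
#' Raising `max_negative` tolerates mild contamination, which matters for
#' real data where even hallmark gluten motifs occasionally appear in
#' non-disease peptides.
#'
#' @param positives,negatives Peptide data frames (labels ignored).
#' @param kmin,kmax Pattern length bounds (defaults 3 and 6).
#' @param min_positive Minimum number of distinct positive sequences
#'   containing the pattern; default `ceiling(1%% of positives)`.
#' @param max_negative Maximum tolerated negative sequences (default 0).
#' @return A tibble of class `motif_set` with columns `pattern`,
#'   `positive_count`, `negative_count`.
#' @examples
#' pos <- peptide_tbl(c("QPFAA", "AQPFA", "QQPFA"))
#' neg <- peptide_tbl(c("AAAAA", "LLLLL"))
#' discover_motifs(pos, neg, kmax = 4, min_positive = 2)
#' @export
discover_motifs <- function(positives, negatives, kmin = 3L, kmax = 6L,
                            min_positive = NULL, max_negative = 0L) {
  check_peptide_df(positives)
  check_peptide_df(negatives)
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  if (kmin < 1L) abort("`kmin` must be >= 1.")
  if (kmin > kmax) abort("`kmin` must be <= `kmax`.")
  if (nrow(positives) == 0L) abort("Positive set is empty.")
  if (is.null(min_positive)) min_positive <- ceiling(0.01 * nrow(positives))
  min_positive <- max(1L, as.integer(min_positive))

  pos_support <- kmer_support(positives$sequence, kmin, kmax)
  candidates <- pos_support[pos_support >= min_positive]
  if (length(candidates) == 0L) return(empty_motif_set())
  neg_support <- count_sequences_containing(names(candidates), negatives$sequence)
  keep <- neg_support <= max_negative
  patterns <- names(candidates)[keep]
  if (length(patterns) == 0L) return(empty_motif_set())
  pos_counts <- unname(candidates[keep])
  neg_counts <- unname(neg_support[keep])

  # substring dominance: drop any pattern that properly contains another
  # retained pattern
  redundant <- vapply(seq_along(patterns), function(i) {
    others <- patterns[-i]
    any(vapply(others, function(q) {
      nchar(q) < nchar(patterns[i]) && grepl(q, patterns[i], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  out <- tibble(
    pattern = patterns[!redundant],
    positive_count = as.integer(pos_counts[!redundant]),
    negative_count = as.integer(neg_counts[!redundant])
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$positive_count), .data$pattern)
  class(out) <- c("motif_set", class(out))
  out
}

empty_motif_set <- function() {
  out <- tibble(
    pattern = character(),
    positive_count = integer(),
    negative_count = integer()
  )
  class(out) <- c("motif_set", class(out))
  out
}

# number of sequences containing each distinct k-mer, k in kmin..kmax
kmer_support <- function(sequences, kmin, kmax) {
  per_seq <- lapply(sequences, function(s) {
    L <- nchar(s)
    ks <- kmin:min(kmax, L)
    ks <- ks[ks <= L]
    if (length(ks) == 0L) return(character())
    unique(unlist(lapply(ks, function(k) {
      substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    })))
  })
  table_to_named_int(unlist(per_seq))
}

table_to_named_int <- function(x) {
  if (length(x) == 0L) return(integer())
  tab <- table(x)
  setNames(as.integer(tab), names(tab))
}

count_sequences_containing <- function(patterns, sequences) {
  vapply(patterns, function(p) {
    sum(stringr::str_detect(sequences, stringr::fixed(p)))
  }, integer(1))
}

#' Scan sequences for motif occurrences
#'
#' Reports every occurrence of every motif, including overlapping ones, with
#' 1-based start positions.
#'
#' @param data Peptide data frame, or a character vector of sequences.
#' @param motifs Motif patterns: a character vector, a `motif_set`, or any
#'   data frame with a `pattern` column.
#' @return A tibble with columns `id`, `motif`, `start`, `end` (1-based,
#'   inclusive), sorted by id (input order), start, then pattern. Empty when
#'   nothing matches.
#' @examples
#' scan_motifs(peptide_tbl("LQLQPFPQPQ"), c("QPF", "PQPQ"))
#' @export
scan_motifs <- function(data, motifs) {
  if (is.character(data)) data <- peptide_tbl(data)
  check_peptide_df(data)
  motifs <- motif_patterns(motifs)
  if (length(motifs) == 0L) abort("`motifs` must contain at least one pattern.")
  hits <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    purrr::map_dfr(motifs, function(m) {
      # zero-width lookahead finds overlapping occurrences
      starts <- gregexpr(paste0("(?=", m, ")"), data$sequence[i], perl = TRUE)[[1L]]
      if (starts[1L] == -1L) return(NULL)
      tibble(
        id = data$id[i],
        motif = m,
        start = as.integer(starts),
        end = as.integer(starts) + nchar(m) - 1L
      )
    })
  })
  if (nrow(hits) == 0L) {
    return(tibble(id = character(), motif = character(),
                  start = integer(), end = integer()))
  }
  hits$`..ord` <- match(hits$id, data$id)
  hits <- dplyr::arrange(hits, .data$`..ord`, .data$start, .data$motif)
  hits$`..ord` <- NULL
  hits
}

motif_patterns <- function(motifs) {
  if (is.data.frame(motifs)) {
    if (!"pattern" %in% names(motifs)) {
      abort("Motif data frames must have a `pattern` column.")
    }
    motifs <- motifs$pattern
  }
  motifs <- toupper(as.character(motifs))
  if (length(motifs)) validate_sequences(motifs, paste0("motif", seq_along(motifs)))
  motifs
}

#' Cumulative motif coverage of a positive set
#'
#' Attributes each positive sequence to the first motif (in the given order)
#' it contains, and tabulates per-motif occurrence, percentage of the
#' positive set, and the running cumulative percentage. Sequences containing
#' none of the motifs form the residual row, labeled `"ML prediction"`: in
#' the ensemble those are the peptides decided by the composition
#' classifier.
#'
#' @param motifs Ordered motif patterns (the attribution order to report).
#' @param positives Peptide data frame of positive sequences.
#' @return A tibble of class `coverage_table` with columns `motif`,
#'   `occurrence`, `percentage`, `cumulative`; the final row is the
#'   residual. Percentages sum to 100 up to rounding.
#' @examples
#' motif_coverage(c("QPF", "QPQ"), peptide_tbl(c("AQPFA", "QPQAA", "LLLLL")))
#' @export
motif_coverage <- function(motifs, positives) {
  check_peptide_df(positives)
  if (nrow(positives) == 0L) abort("Positive set is empty.")
  motifs <- motif_patterns(motifs)
  n <- nrow(positives)
  attributed <- rep(NA_character_, n)
  for (m in motifs) {
    free <- is.na(attributed)
    hit <- free & stringr::str_detect(positives$sequence, stringr::fixed(m))
    attributed[hit] <- m
  }
  counts <- vapply(motifs, function(m) sum(attributed == m, na.rm = TRUE), integer(1))
  residual <- sum(is.na(attributed))
  out <- tibble(
    motif = c(motifs, "ML prediction"),
    occurrence = c(unname(counts), residual),
    percentage = c(unname(counts), residual) / n * 100
  )
  out$cumulative <- cumsum(out$percentage)
  class(out) <- c("coverage_table", class(out))
  out
}

#' The published celiac-disease motif set
#'
#' The hallmark ungapped motifs of CD-associated (gluten-derived) peptides
#' -- QPF, PYP, PEQ, QPQ and relatives -- shipped as the package's
#' pretrained motif set, ordered by their occurrence among known positives
#' so that first-match coverage attribution reports the dominant motifs
#' first. Counts are occurrences among catalogued CD-associated peptides.
#'
#' @return A `motif_set` tibble (`pattern`, `positive_count`,
#'   `negative_count`).
#' @examples
#' celiac_motifs()
#' @export
celiac_motifs <- function() {
  read_motifs(system.file("extdata", "celiac_motifs.tsv",
                          package = "celiacpep", mustWork = TRUE))
}

#' Read a motif list file
#'
#' One pattern per line; optionally two further tab-separated columns with
#' positive and negative occurrence counts.
#'
#' @param path Path to the motif file.
#' @return A `motif_set` tibble.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  out <- tibble(
    pattern = toupper(vapply(parts, `[`, character(1), 1L)),
    positive_count = vapply(parts, function(p) {
      if (length(p) >= 2L) as.integer(p[2L]) else NA_integer_
    }, integer(1)),
    negative_count = vapply(parts, function(p) {
      if (length(p) >= 3L) as.integer(p[3L]) else NA_integer_
    }, integer(1))
  )
  validate_sequences(out$pattern, out$pattern)
  class(out) <- c("motif_set", class(out))
  out
}
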