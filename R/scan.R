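#' Scan a protein for CD-associated regions
#'
#' Slides a window along a protein, scores every window with the chosen
#' predictor (ensemble, composition classifier or PQ-density), and reports
#' all windows with 1-based inclusive coordinates. High-scoring regions of
#' food or therapeutic proteins are candidate immunogenic fragments.
#'
#' @param protein A single-row peptide data frame, a named character vector,
#'   or a plain sequence string.
#' @param predictor A fitted predictor accepted by [peptide_scores()].
#' @param window_length Window size in residues (default 9, the minimum
#'   epitope length).
#' @param step Stride between window starts (default 1, fully overlapping).
#' @param positive_only Keep only windows called positive (default FALSE).
#' @return A tibble of class `protein_scan` with columns `protein_id`,
#'   `start`, `end`, `subsequence`, `score`, `label` (plus `provenance` /
#'   `matched_motif` for ensembles); `floor((L - w)/step) + 1` rows in
#'   N-to-C order before filtering.
#' @examples
#' scan_protein("AAAAAAPQPQPQPQPAAAAA", pq_classifier(), window_length = 9)
#' @export
scan_protein <- function(protein, predictor, window_length = 9L, step = 1L,
                         positive_only = FALSE) {
  if (is.character(protein)) {
    protein <- peptide_tbl(protein,
                           id = names(protein) %||% "protein1")
  }
  check_peptide_df(protein)
  if (nrow(protein) != 1L) abort("`scan_protein()` scans one protein at a time.")
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (step < 1L) abort("`step` must be >= 1.")
  L <- nchar(protein$sequence)
  if (window_length > L) {
    abort(paste0(
      "`window_length` (", window_length, ") exceeds protein length (", L, ")."
    ))
  }
  starts <- seq.int(1L, L - window_length + 1L, by = step)
  windows <- tibble(
    id = paste0(protein$id, "_", starts, "-", starts + window_length - 1L),
    sequence = substring(protein$sequence, starts, starts + window_length - 1L)
  )
  scored <- peptide_scores(predictor, windows)
  out <- dplyr::bind_cols(
    tibble(
      protein_id = protein$id,
      start = starts,
      end = starts + window_length - 1L,
      subsequence = windows$sequence
    ),
    scored[, setdiff(names(scored), "id"), drop = FALSE]
  )
  if (positive_only) out <- dplyr::filter(out, .data$label == "positive")
  class(out) <- c("protein_scan", class(out))
  out
}

#' Write scan results as BED
#'
#' BED uses 0-based half-open coordinates; everywhere else in the package
#' positions are 1-based inclusive.
#'
#' @param scan A `protein_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_bed <- function(scan, path) {
  stopifnot(is.data.frame(scan),
            all(c("protein_id", "start", "end", "label", "score") %in% names(scan)))
  readr::write_tsv(
    tibble(
      chrom = scan$protein_id,
      chromStart = scan$start - 1L,
      chromEnd = scan$end,
      name = scan$label,
      score = scan$score
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Exhaustive single-substitution analog design
#'
#' Generates every single-position substitution of a peptide to each of the
#' other 19 residues (19 * L analogs), scores the parent and every analog
#' with the chosen predictor, and reports them parent-first. Useful for
#' mapping which residues drive a positive call -- e.g. substituting away
#' the only prolines/glutamines of a gluten fragment lowers its PQ-density
#' score.
#'
#' @param peptide A single peptide (data frame row, named vector or string).
#' @param predictor A fitted predictor accepted by [peptide_scores()].
#' @return A tibble of class `analog_set`: `position` (1-based, 0 for the
#'   parent), `original`, `substituted`, `sequence`, `score`, `label`.
#' @examples
#' design_analogs("QPQLPYPQP", pq_classifier())
#' @export
design_analogs <- function(peptide, predictor) {
  if (is.character(peptide)) {
    peptide <- peptide_tbl(peptide, id = names(peptide) %||% "parent")
  }
  check_peptide_df(peptide)
  if (nrow(peptide) != 1L) abort("`design_analogs()` takes one peptide.")
  seq <- peptide$sequence
  L <- nchar(seq)
  residues <- strsplit(seq, "")[[1L]]
  grid <- tidyr::expand_grid(position = seq_len(L), substituted = AA_ALPHABET)
  grid$original <- residues[grid$position]
  grid <- dplyr::filter(grid, .data$substituted != .data$original)
  grid$sequence <- purrr::map2_chr(grid$position, grid$substituted, function(p, r) {
    s <- residues
    s[p] <- r
    paste(s, collapse = "")
  })
  all_rows <- dplyr::bind_rows(
    tibble(position = 0L, original = NA_character_,
           substituted = NA_character_, sequence = seq),
    grid[, c("position", "original", "substituted", "sequence")]
  )
  scored <- peptide_scores(
    predictor,
    peptide_tbl(all_rows$sequence,
                id = paste0(peptide$id, "_", seq_len(nrow(all_rows))))
  )
  all_rows$score <- scored$score
  all_rows$label <- scored$label
  class(all_rows) <- c("analog_set", class(all_rows))
  all_rows
}
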