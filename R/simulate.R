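#' Default residue composition of simulated CD-like positives
#'
#' A stylised gluten-like composition: strongly proline/glutamine-enriched
#' with elevated phenylalanine, leucine and tyrosine (P 0.28, Q 0.28,
#' F 0.08, L 0.08, Y 0.06; the remaining 15 residues share the rest
#' uniformly). Mirrors the compositional signature of catalogued
#' CD-associated peptides at a qualitative level.
#'
#' @return Named numeric probability vector over the 20 residues (sums to 1).
#' @export
positive_composition <- function() {
  comp <- setNames(rep(0, 20), AA_ALPHABET)
  comp[c("P", "Q", "F", "L", "Y")] <- c(0.28, 0.28, 0.08, 0.08, 0.06)
  rest <- setdiff(AA_ALPHABET, c("P", "Q", "F", "L", "Y"))
  comp[rest] <- (1 - sum(comp)) / length(rest)
  comp
}

#' Default residue composition of simulated background negatives
#'
#' Approximately uniform with mildly elevated leucine, alanine and serine
#' (L 0.10, A 0.08, S 0.07), loosely following the average proteome
#' background; proline and glutamine sit near 4.4% each.
#'
#' @return Named numeric probability vector over the 20 residues (sums to 1).
#' @export
background_composition <- function() {
  comp <- setNames(rep(0, 20), AA_ALPHABET)
  comp[c("L", "A", "S")] <- c(0.10, 0.08, 0.07)
  rest <- setdiff(AA_ALPHABET, c("L", "A", "S"))
  comp[rest] <- (1 - sum(comp)) / length(rest)
  comp
}

#' Default motif pool planted in simulated positives
#'
#' The eight hallmark CD motifs used by the generator: QPF, QQPF, PYP, PEQ,
#' QPQ, PQPQ, QQPQ, PQL.
#'
#' @return Character vector of patterns.
#' @export
default_motif_pool <- function() {
  c("QPF", "QQPF", "PYP", "PEQ", "QPQ", "PQPQ", "QQPQ", "PQL")
}

#' Simulate a labeled CD-like peptide dataset
#'
#' Generates positives and negatives with the statistical structure the
#' prediction method assumes, so every stage of the pipeline can be
#' exercised end-to-end without external data. Positive peptides draw their
#' length uniformly from `length_range` and their residues i.i.d. from the
#' P/Q-rich `positive_composition`; a designated fraction
#' (`motif_plant_fraction`, chosen exactly: `round(fraction * n_positive)`
#' peptides) receives one motif from `motif_pool` written over a random
#' in-bounds window, while the remaining positives are resampled until they
#' contain no pool motif, so the fraction of motif-bearing positives is
#' exact. Negatives draw from the near-uniform background composition and
#' are resampled until free of every pool motif (unless
#' `leaky_negative_fraction > 0`, in which case that fraction of negatives
#' gets a pool motif planted, emulating the mild contamination seen in real
#' non-disease peptides). Sequences are unique within each class and the
#' output is deterministic given `seed`.
#'
#' @param n_positive,n_negative Class sizes (defaults 500 each, the scale of
#'   curated CD epitope collections).
#' @param seed Integer seed; same seed, same dataset.
#' @param length_range Inclusive peptide length bounds, default `c(9, 20)`.
#' @param positive_comp,negative_comp Named probability vectors over the 20
#'   residues; defaults [positive_composition()] /
#'   [background_composition()].
#' @param motif_pool Patterns available for planting; default
#'   [default_motif_pool()].
#' @param motif_plant_fraction Fraction of positives carrying at least one
#'   pool motif (default 0.8).
#' @param leaky_negative_fraction Fraction of negatives carrying a planted
#'   pool motif (default 0).
#' @param max_attempts Resampling bound per record before giving up.
#' @return A labeled peptide tibble (`id`, `sequence`, `label`), positives
#'   first.
#' @examples
#' d <- simulate_peptides(n_positive = 20, n_negative = 20, seed = 42)
#' table(d$label)
#' @export
simulate_peptides <- function(n_positive = 500L, n_negative = 500L, seed = 1L,
                              length_range = c(9L, 20L),
                              positive_comp = positive_composition(),
                              negative_comp = background_composition(),
                              motif_pool = default_motif_pool(),
                              motif_plant_fraction = 0.8,
                              leaky_negative_fraction = 0,
                              max_attempts = 1000L) {
  stopifnot(n_positive >= 1L, n_negative >= 1L,
            motif_plant_fraction >= 0, motif_plant_fraction <= 1,
            leaky_negative_fraction >= 0, leaky_negative_fraction <= 1)
  check_composition(positive_comp)
  check_composition(negative_comp)
  motif_pool <- motif_patterns(motif_pool)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n_plant_pos <- round(motif_plant_fraction * n_positive)
  planted_pos <- sample(n_positive) <= n_plant_pos
  pos <- sample_class(
    n_positive, length_range, positive_comp, motif_pool,
    planted = planted_pos, max_attempts = max_attempts
  )

  n_plant_neg <- round(leaky_negative_fraction * n_negative)
  planted_neg <- sample(n_negative) <= n_plant_neg
  neg <- sample_class(
    n_negative, length_range, negative_comp, motif_pool,
    planted = planted_neg, max_attempts = max_attempts
  )

  tibble(
    id = c(paste0("pos", seq_len(n_positive)), paste0("neg", seq_len(n_negative))),
    sequence = c(pos, neg),
    label = rep(c("positive", "negative"), c(n_positive, n_negative))
  )
}

check_composition <- function(comp) {
  if (is.null(names(comp)) || !setequal(names(comp), AA_ALPHABET)) {
    abort("Compositions must be named probability vectors over the 20 residues.")
  }
  if (abs(sum(comp) - 1) > 1e-9 || any(comp < 0)) {
    abort("Composition probabilities must be non-negative and sum to 1.")
  }
  invisible(comp)
}

contains_any <- function(sequence, patterns) {
  any(stringr::str_detect(sequence, stringr::fixed(patterns)))
}

# one class: unique sequences; planted records carry >= 1 pool motif,
# unplanted records carry none (rejection sampling)
sample_class <- function(n, length_range, comp, motif_pool, planted,
                         max_attempts) {
  comp <- comp[AA_ALPHABET]
  seen <- character()
  out <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      L <- sample(seq.int(length_range[1L], length_range[2L]), 1L)
      s <- paste(sample(AA_ALPHABET, L, replace = TRUE, prob = comp),
                 collapse = "")
      if (planted[i]) {
        motif <- sample(motif_pool, 1L)
        if (nchar(motif) > L) next
        at <- sample.int(L - nchar(motif) + 1L, 1L)
        substr(s, at, at + nchar(motif) - 1L) <- motif
      } else if (contains_any(s, motif_pool)) {
        next
      }
      if (!s %in% seen) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste0(
        "Could not generate a valid unique sequence after ", max_attempts,
        " attempts; increase the alphabet mass outside P/Q or relax settings."
      ))
    }
    seen <- c(seen, s)
    out[i] <- s
  }
  out
}

#' Write a simulated dataset as a FASTA fixture
#'
#' Writes a positive and a negative FASTA file plus a JSON manifest
#' recording the generator settings, seed and MD5 checksums, so the fixture
#' can be verified and regenerated exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param ... Arguments passed to [simulate_peptides()].
#' @param seed Integer seed (recorded in the manifest).
#' @return Invisibly, a list with `positive`, `negative` and `manifest`
#'   paths.
#' @export
write_peptide_fixture <- function(out_dir, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- simulate_peptides(seed = seed, ...)
  pos_path <- file.path(out_dir, "positive.fasta")
  neg_path <- file.path(out_dir, "negative.fasta")
  write_peptide_fasta(data[data$label == "positive", ], pos_path)
  write_peptide_fasta(data[data$label == "negative", ], neg_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  settings <- list(...)
  manifest <- list(
    generator = "celiacpep::simulate_peptides",
    seed = as.integer(seed),
    settings = if (length(settings)) settings else NULL,
    n_positive = sum(data$label == "positive"),
    n_negative = sum(data$label == "negative"),
    md5 = list(
      positive = unname(tools::md5sum(pos_path)),
      negative = unname(tools::md5sum(neg_path))
    )
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(positive = pos_path, negative = neg_path,
                 manifest = manifest_path))
}
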