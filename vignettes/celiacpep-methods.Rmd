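---
title: "Methods behind celiacpep: PQ density, exclusive motifs, composition classifiers and the motif-first ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind celiacpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celiacpep)
```

## The problem

Celiac disease is driven by gluten-derived peptides that survive digestion
and are presented by HLA-DQ2/DQ8 to T cells. Catalogued CD-associated
epitopes are short (9–20 residues) and compositionally extreme: proline and
glutamine dominate, phenylalanine is elevated, and short motifs such as
QPF, QPQ and PYP recur across otherwise distinct peptides. `celiacpep`
operationalises this signature as three predictors of increasing
complexity — a one-parameter window statistic, an exclusive-motif scanner,
and a 20-feature composition classifier — plus an ensemble that combines
the last two. This vignette records the models, their parameters, the
numerical conventions, and the reasoning behind the design choices that
the data structures do not make self-evident.

## PQ density

For a peptide $s$ of length $L$ and a window width $w$, every one of the
$L - w + 1$ overlapping windows is scored by its P+Q fraction, and the
peptide's score is the maximum:

$$\mathrm{pq}(s; w) \;=\; \max_{1 \le i \le L-w+1}\;
\frac{\#\{j \in [i, i+w-1] : s_j \in \{P, Q\}\}}{w}.$$

The maximum (rather than the mean) matters: immunogenic fragments carry a
locally dense P/Q core even when their flanks are unremarkable. Scores are
exact rationals $k/w$, which keeps threshold comparisons reproducible.

Conventions, chosen once and used everywhere:

- **Step 1 windows.** Overlapping enumeration with stride one; any larger
  stride could miss the maximal window.
- **Threshold grid 0 to 1 in steps of 0.01.** Published operating points
  for this family of statistics are printed at two to three decimals, and a
  hundredths grid resolves every achievable $k/w$ score boundary for
  $w \le 9$ closely enough that the balanced point is stable.
- **Balanced selection with explicit tie-breaks.** The selected threshold
  minimises $|\mathrm{Sens} - \mathrm{Spec}|$; ties go to the higher
  accuracy, then to the smaller threshold. The last rule makes perfectly
  separated data select the smallest strictly separating grid point rather
  than an arbitrary one.
- **Positive at the boundary.** A peptide is called positive when
  score $\ge$ threshold. The direction is a convention; tests pin it so it
  cannot drift.
- **Short peptides are skipped, not padded**, in the window-size sweep: a
  zero-padded window would dilute the statistic with fictitious residues.
  The number skipped per window size is reported.

`pq_classifier()` defaults to window 5 and threshold 0.41. Window 5 is the
best-performing width on balanced data in this method family, and 0.41 is
the balanced operating point the package's own tuning reproduces on its
reference synthetic study (`tune_pq_threshold()` re-derives it from data in
the acceptance script rather than trusting the constant).

## Class-exclusive motifs

Discovery enumerates every ungapped substring of length `kmin`–`kmax`
(defaults 3–6) found in the positive set and keeps a pattern when

- at least `min_positive` positive sequences contain it (default: 1% of
  the positive set, rounded up — small enough to find rare-but-real
  patterns, large enough to exclude singletons), and
- at most `max_negative` negative sequences contain it (default 0, i.e.
  strict class exclusivity; real datasets show hallmark motifs leaking
  into a handful of non-disease peptides, so the bound is a parameter).

Counts are per-sequence: a peptide containing a motif three times supports
it once. After filtering, a **substring-dominance** rule removes redundant
patterns: if a retained pattern is a proper substring of another candidate,
the longer one is dropped (any sequence containing the longer pattern
necessarily contains the shorter, so the shorter covers a superset of
positives and scans strictly more generally). This post-filter is this
package's construction — frequent-pattern mining offers several
canonical-form choices (closed, maximal, generator patterns) and none
reproduces the published result surface of this method family better than
plain substring dominance. The result is ordered by positive support
descending, ties lexicographic.

Motifs here are exact ungapped literals. Gapped or degenerate motif classes
(as in general-purpose motif-extraction programs) are out of scope: the
hallmark CD motifs are all short literals, and literal scanning keeps
every downstream guarantee (precedence, coverage attribution) exact.

Coverage reporting (`motif_coverage()`) attributes each positive sequence
to the *first* motif in the listed order that it contains, yielding a
cumulative coverage column that ends at 100%; the residual row counts the
sequences no motif matches — exactly the peptides the ensemble's
classifier path must decide, which is why the row is labeled
`ML prediction`. The shipped motif set (`celiac_motifs()`) is ordered by
occurrence among catalogued positives so the dominant motifs absorb
attribution first.

## Composition classifiers

Each peptide is represented by its amino-acid composition,
$\mathrm{AAC}_i = 100\, R_i / L$ for the 20 standard residues in fixed
alphabetical column order; rows sum to 100 exactly. Composition discards
positional information deliberately — at 9–20 residues, P/Q content is the
dominant class signal and a 20-dimensional representation trains reliably
on a few hundred examples.

The evaluation protocol is a stratified 80:20 hold-out (per-class
validation size `round(0.2 n)`), with five stratified cross-validation
folds (per-class sizes within one of each other) on the training portion.
The reported *training* metrics are the unweighted mean of the five
per-fold rows; the model is then refit on the full 80% and scored once on
the untouched 20%. Splits, folds and every stochastic fit are driven by a
single user seed, and training is deterministic given (data, kind, seed).

Eight classifier kinds are supported behind one interface, with fixed
hyperparameter defaults recorded in the fitted object (no tuning
protocol is applied): decision tree (`rpart`), random forest and
extremely randomised trees (`ranger`, 500 trees; ET uses the
`extratrees` split rule without bootstrapping), logistic regression
(`glm`), gradient boosting (`xgboost`, 100 rounds, depth 4, learning rate
0.3, single thread), k-nearest neighbours (`class::knn`, k = 5, vote
fractions as scores), Gaussian naive Bayes and an RBF support-vector
classifier (`e1071`; SVC scores are Platt-scaled probabilities). Scores
are positive-class probabilities in $[0,1]$; labels use score $\ge$ 0.5
unless the model's threshold is changed. The default deployed kind is ET,
the strongest member of this panel on composition features. Threshold
metrics follow the standard closed forms; MCC is defined as 0 when a
marginal of the confusion matrix is zero, and AUROC is computed by the
rank-sum (Mann–Whitney) formulation with average ranks for ties, which the
tests verify equals trapezoidal ROC integration to $10^{-9}$.

## The motif-first ensemble

`ensemble_model()` pairs an ordered motif set with a fitted composition
classifier. The rule has strict precedence: any peptide containing any
motif of the set is positive with provenance `motif` (the classifier is
not consulted); only motif-free peptides are decided by the classifier
score against `ml_threshold` (default 0.5). Motifs can only assert
positives — there is no negative-motif veto — so adding motifs can only
move motif-free decisions from the classifier column into the motif
column, and the tests assert that motif-bearing peptides are called
positive even against a classifier deliberately trained to score them low.
Every prediction records provenance and, on the motif path, the first
matching motif in set order.

## Protein scanning and analog design

`scan_protein()` slides a window (default 9 residues — the minimum epitope
length; stride default 1) along a protein and scores each window with any
predictor (PQ, ML, ensemble) through the common `peptide_scores()`
interface; row count is $\lfloor (L-w)/\text{step} \rfloor + 1$. All
user-facing coordinates are 1-based inclusive; the optional BED writer is
the single place 0-based half-open coordinates appear.
`design_analogs()` enumerates all $19L$ single-residue substitutions plus
the parent (reported first) and scores them identically; substituting away
a peptide's only P/Q residues can never raise its PQ score, which the
tests use as a monotonicity check.

## The synthetic generator

`simulate_peptides()` produces the study conditions every end-to-end test
runs under: positives draw lengths uniformly from 9–20 and residues i.i.d.
from a stylised gluten-like composition (P 0.28, Q 0.28, F 0.08, L 0.08,
Y 0.06, remainder uniform); negatives draw from a near-uniform proteome
background (L 0.10, A 0.08, S 0.07). Exactly `round(0.8 n)` positives (the
default plant fraction) receive one of the eight hallmark motifs written
over a random in-bounds window; the remaining positives and all negatives
are rejection-resampled until they contain no pool motif. Making the
motif-bearing fraction *exact* (rather than binomial) is deliberate: the
ensemble's provenance accounting is tested against it. A
`leaky_negative_fraction` option plants motifs into a fraction of
negatives to emulate the mild contamination real non-disease peptides
show. Sequences are unique within class, resampling is bounded (1000
attempts) with a clear error on exhaustion, and output is byte-identical
for a given seed.

The generator emulates composition enrichment, planted literal motifs, the
9–20 length rule and class-pure motif occurrence. It does **not** emulate
positional conservation along the termini-aligned frame, deamidation
biology, HLA restriction, homology clusters among real epitopes (real
gliadin fragments are highly redundant; generated peptides are i.i.d.), or
the label noise of curated databases. Passing tests on this generator
therefore demonstrate correctness of the machinery and separability under
the stated assumptions — not expected performance on curated epitope data,
whose published headline numbers require the original external datasets.

The reference study size is 500+500 peptides with an 80:20 split — the
scale of curated CD epitope collections — and the acceptance script
(`scripts/acceptance.R`) re-runs that study from scratch at any seed.

## Degenerate inputs and edge conventions

- Non-standard residues (B, J, O, U, X, Z) are rejected at ingest with the
  record and character named, not silently skipped: composition and PQ
  density are defined only over the 20-letter alphabet. How curated
  datasets handled such residues is unstated in the literature this
  package follows; rejection is this package's choice.
- Empty sequences, windows longer than the peptide, single-class tuning
  or training inputs, and unreadable model bundles all raise targeted
  errors rather than producing degenerate numbers.
- FASTA ids are the header up to the first whitespace; duplicates gain a
  numeric suffix. TSV datasets are two columns (sequence, 1/0 label) with
  header auto-detection.
- The 18-residue termini vector (first nine plus last nine residues)
  aligns variable-length peptides into a fixed frame; for a 9-mer both
  halves coincide, and an 18-mer maps to itself.

## Known limitations

- Motif discovery is exhaustive over literal k-mers up to length 6;
  longer or degenerate patterns are represented only through their
  literal substrings.
- The classifier panel uses fixed default hyperparameters; no search is
  performed, so panel rankings on new data should be read accordingly.
- KNN stores its training matrix in the fitted object; model bundles for
  KNN scale with the training set.
- Class imbalance is passed through unchanged (no resampling); metrics
  are reported per class, so imbalanced datasets should be read via
  sensitivity/specificity rather than accuracy.
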