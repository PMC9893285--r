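test_that("FASTA reading normalises case, preserves order, validates alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "qpqlpypqpq", ">p2", "ACDEF", "GHIK"), f)
  d <- read_peptide_fasta(f)
  expect_equal(d$id, c("p1", "p2"))
  expect_equal(d$sequence, c("QPQLPYPQPQ", "ACDEFGHIK"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACDEF", ">hasB", "ACBDE"), bad)
  expect_error(read_peptide_fasta(bad), "hasB.*B", ignore.case = FALSE)

  headless <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACDEF", ">p1", "ACDEF"), headless)
  expect_error(read_peptide_fasta(headless), "line 1")
})

test_that("FASTA write/read round-trips ids and sequences exactly", {
  d <- peptide_tbl(
    c("QPQLPYPQPQ", "ACDEFGHIKLMNPQRSTVWY", "PPPPPPPPP"),
    id = c("a", "b", "c_1")
  )
  f <- withr::local_tempfile(fileext = ".fasta")
  write_peptide_fasta(d, f)
  expect_equal(read_peptide_fasta(f), d)
})

test_that("TSV reading handles 1/0 labels with and without a header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("QPQLPYPQPQ\t1", "ACDEFGHIK\t0"), f)
  d <- read_peptide_tsv(f)
  expect_equal(d$label, c("positive", "negative"))

  fh <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tlabel", "QPQLPYPQPQ\t1", "ACDEFGHIK\t0"), fh)
  expect_equal(read_peptide_tsv(fh)$sequence, d$sequence)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_tsv(d, out)
  expect_equal(read_peptide_tsv(out), d)
})

test_that("length filtering keeps the 9-20 boundary inclusively and dedups per class", {
  d <- peptide_tbl(
    c(
      strrep("A", 8), strrep("C", 9), strrep("D", 20), strrep("E", 21),
      strrep("C", 9), paste0(strrep("C", 8), "A")
    ),
    label = c(1, 1, 1, 1, 1, 0)
  )
  out <- filter_peptides(d)
  expect_equal(nchar(out$sequence), c(9, 20, 9))
  # duplicate positive removed, but the same length-9 sequence shape in the
  # negative class is a different sequence and stays
  expect_equal(out$label, c("positive", "positive", "negative"))
  expect_equal(nrow(filter_peptides(peptide_tbl(character()))), 0)

  dup <- peptide_tbl(c("ACDEFGHIK", "ACDEFGHIK"), label = c(1, 0))
  expect_equal(nrow(filter_peptides(dup)), 2) # dedup is within-class only
})

test_that("termini vector concatenates N- and C-terminal 9-mers", {
  expect_equal(termini_vector("ACDEFGHIK"), "ACDEFGHIKACDEFGHIK")
  expect_equal(termini_vector("ACDEFGHIKLMN"), "ACDEFGHIKEFGHIKLMN")
  an18 <- paste(rep(c("A", "C"), 9), collapse = "")
  expect_equal(termini_vector(an18), an18)
  expect_error(termini_vector("ACDEFGHI"), ">= 9")
  # property: always 18 residues
  set.seed(11)
  for (i in 1:50) expect_equal(nchar(termini_vector(random_peptide())), 18)
})

test_that("amino-acid composition matches hand counts and always sums to 100", {
  v <- aac_composition("PPPPPPPPPP")
  expect_equal(unname(v["P"]), 100)
  expect_equal(sum(v), 100)

  v2 <- aac_composition("QPQLPYPQPQ")
  expect_equal(unname(v2[c("Q", "P", "L", "Y")]), c(40, 40, 10, 10))
  expect_equal(unname(v2["A"]), 0)

  set.seed(7)
  for (i in 1:200) {
    expect_equal(sum(aac_composition(random_peptide(1, 30))), 100,
                 tolerance = 1e-12)
  }
  expect_error(aac_composition(""), "Empty")
})

test_that("feature matrix has fixed alphabetical column order and row sums of 100", {
  d <- peptide_tbl(c("PPPPPPPPPP", "QPQLPYPQPQ", "ACDEFGHIK"), label = c(1, 1, 0))
  ft <- aac_features(d)
  aa_cols <- setdiff(names(ft), c("id", "label"))
  expect_equal(aa_cols, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(unname(rowSums(ft[, aa_cols])), rep(100, 3))
  expect_equal(ft$P[1], 100)
  expect_equal(unlist(ft[2, c("Q", "P", "L", "Y")], use.names = FALSE),
               c(40, 40, 10, 10))
})

test_that("invalid residues are rejected at ingest with record and character named", {
  expect_error(peptide_tbl("ACBX", id = "r1"), "r1.*B")
  expect_error(peptide_tbl(c("ACD", "")), "Empty")
  expect_error(peptide_tbl("ACD", label = "maybe"), "Unrecognised label")
})

test_that("duplicate ids are disambiguated with numeric suffixes", {
  d <- peptide_tbl(c("ACDEF", "GHIKL", "MNPQR"), id = c("x", "x", "x"))
  expect_equal(d$id, c("x", "x_2", "x_3"))
})
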