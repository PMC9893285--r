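test_that("discovery on the three-sequence example matches the exhaustive oracle", {
  pos <- peptide_tbl(c("QPFAA", "AQPFA", "QQPFA"))
  neg <- peptide_tbl(c("AAAAA", "LLLLL"))
  got <- discover_motifs(pos, neg, kmin = 3, kmax = 4,
                         min_positive = 2, max_negative = 0)
  want <- brute_discover(pos$sequence, neg$sequence, 3, 4, 2, 0)
  expect_equal(as.data.frame(got), want)
  # QPF is recovered with full support and class exclusivity; its
  # superstring QPFA is pruned as redundant
  expect_true("QPF" %in% got$pattern)
  expect_equal(got$positive_count[got$pattern == "QPF"], 3L)
  expect_equal(got$negative_count[got$pattern == "QPF"], 0L)
  expect_false("QPFA" %in% got$pattern)
})

test_that("discovery equals the brute-force oracle on random datasets", {
  set.seed(202)
  for (rep in 1:25) {
    pos <- sapply(1:sample(5:20, 1), function(i) random_peptide(5, 12))
    neg <- sapply(1:sample(5:20, 1), function(i) random_peptide(5, 12))
    minp <- sample(1:3, 1)
    maxn <- sample(0:1, 1)
    got <- discover_motifs(
      peptide_tbl(unique(pos)), peptide_tbl(unique(neg)),
      kmin = 3, kmax = 5, min_positive = minp, max_negative = maxn
    )
    want <- brute_discover(unique(pos), unique(neg), 3, 5, minp, maxn)
    expect_equal(as.data.frame(got), want)
  }
})

test_that("identical positive and negative sets admit no exclusive motif", {
  d <- peptide_tbl(c("QPFQPF", "PYPPYP"))
  expect_equal(nrow(discover_motifs(d, d, min_positive = 1)), 0)
})

test_that("every discovered motif really occurs in enough positives", {
  d <- default_study()
  pos <- d[d$label == "positive", ]
  neg <- d[d$label == "negative", ]
  motifs <- discover_motifs(pos, neg, min_positive = 25)
  expect_gt(nrow(motifs), 0)
  for (i in seq_len(nrow(motifs))) {
    n <- sum(grepl(motifs$pattern[i], pos$sequence, fixed = TRUE))
    expect_equal(n, motifs$positive_count[i])
    expect_gte(n, 25)
    expect_equal(sum(grepl(motifs$pattern[i], neg$sequence, fixed = TRUE)), 0)
  }
  # ordering: positive support descending
  expect_true(all(diff(motifs$positive_count) <= 0))
})

test_that("planted motifs are recovered (as themselves or sub/superstrings)", {
  d <- default_study()
  motifs <- discover_motifs(
    d[d$label == "positive", ], d[d$label == "negative", ],
    min_positive = ceiling(0.05 * 500), max_negative = 0
  )
  recovered <- sapply(default_motif_pool(), function(p) {
    any(sapply(motifs$pattern, function(m) {
      grepl(m, p, fixed = TRUE) || grepl(p, m, fixed = TRUE)
    }))
  })
  expect_true(all(recovered))
})

test_that("motif scanning reports all overlapping occurrences, 1-based", {
  hits <- scan_motifs(peptide_tbl("LQLQPFPQPQ", id = "q"), c("QPF", "PQPQ"))
  expect_equal(hits$motif, c("QPF", "PQPQ"))
  expect_equal(hits$start, c(4L, 7L))
  expect_equal(hits$end, c(6L, 10L))

  overlap <- scan_motifs("QPQPQ", "QPQ")
  expect_equal(overlap$start, c(1L, 3L))

  expect_equal(nrow(scan_motifs("AAAA", "QPF")), 0)
})

test_that("scanning equals naive per-position comparison on random inputs", {
  set.seed(303)
  for (rep in 1:50) {
    s <- random_peptide(10, 40, prob = rep(c(4, 1), c(4, 16)) / 32)
    pats <- unique(sapply(1:4, function(i) random_peptide(2, 4, prob = rep(c(4, 1), c(4, 16)) / 32)))
    got <- scan_motifs(peptide_tbl(s, id = "s"), pats)
    want <- naive_scan(s, sort(pats))
    expect_equal(got$start, want$start)
    expect_equal(got$motif, want$motif)
  }
})

test_that("coverage attribution is first-match and sums to 100 percent", {
  pos <- peptide_tbl(c("AQPFA", "QPQAA", "LLLLL"))
  cov <- motif_coverage(c("QPF", "QPQ"), pos)
  expect_equal(cov$motif, c("QPF", "QPQ", "ML prediction"))
  expect_equal(cov$occurrence, c(1L, 1L, 1L))
  expect_equal(cov$percentage, rep(100 / 3, 3))
  expect_equal(cov$cumulative[3], 100)

  # a sequence containing both motifs goes to the earlier-listed one only
  both <- peptide_tbl("AQPFQPQAA")
  cov2 <- motif_coverage(c("QPF", "QPQ"), both)
  expect_equal(cov2$occurrence, c(1L, 0L, 0L))

  # full coverage leaves an empty residual
  cov3 <- motif_coverage("QPF", peptide_tbl(c("AQPFA", "QPFAA")))
  expect_equal(cov3$occurrence[cov3$motif == "ML prediction"], 0L)
  expect_equal(cov3$cumulative[1], 100)

  # no coverage puts everything in the residual
  cov4 <- motif_coverage("WWW", pos)
  expect_equal(cov4$occurrence, c(0L, 3L))
})

test_that("cumulative coverage is non-decreasing and bounded", {
  d <- default_study()
  pos <- d[d$label == "positive", ]
  cov <- motif_coverage(default_motif_pool(), pos)
  expect_true(all(diff(cov$cumulative) >= -1e-9))
  expect_equal(cov$cumulative[nrow(cov)], 100, tolerance = 1e-9)
  expect_equal(sum(cov$occurrence), nrow(pos))
})

test_that("the shipped motif set loads with patterns and counts", {
  m <- celiac_motifs()
  expect_s3_class(m, "motif_set")
  expect_equal(m$pattern[1], "QPF")
  expect_true(all(c("QPQ", "PYP", "PEQ", "PQPQ", "QQPF") %in% m$pattern))
  expect_equal(m$positive_count[m$pattern == "QPQ"], 350L)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", m$pattern)))
})
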