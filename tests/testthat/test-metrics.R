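test_that("confusion counts match hand-tabulated cases", {
  expect_equal(
    unlist(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))),
    c(tp = 2L, tn = 2L, fp = 0L, fn = 0L)
  )
  expect_equal(
    unlist(confusion_counts(c(1, 0), c(0, 1))),
    c(tp = 0L, tn = 0L, fp = 1L, fn = 1L)
  )
  expect_equal(
    unlist(confusion_counts(c(1, 1, 1, 0), c(1, 0, 1, 0))),
    c(tp = 2L, tn = 1L, fp = 0L, fn = 1L)
  )
  # label encodings are interchangeable
  expect_equal(
    confusion_counts(c("positive", "negative"), c(TRUE, FALSE)),
    confusion_counts(c(1, 0), c(1, 0))
  )
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metric formulas match hand evaluation", {
  m <- classification_metrics(30, 40, 10, 20)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 70)
  expect_equal(m$f1, 0.6667, tolerance = 1e-4)
  expect_lt(abs(m$mcc - 0.4082), 1e-4)

  perfect <- classification_metrics(50, 50, 0, 0)
  expect_equal(
    unlist(perfect),
    c(sensitivity = 100, specificity = 100, accuracy = 100, f1 = 1, mcc = 1)
  )

  worst <- classification_metrics(0, 0, 5, 5)
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$mcc, -1)

  degenerate <- classification_metrics(0, 10, 0, 0) # no positives at all
  expect_equal(degenerate$mcc, 0)
})

test_that("metrics agree with independent formula evaluation on random matrices", {
  set.seed(404)
  for (i in 1:1000) {
    cc <- sample(0:50, 4, replace = TRUE)
    if (sum(cc) == 0) cc[1] <- 1
    tp <- cc[1]; tn <- cc[2]; fp <- cc[3]; fn <- cc[4]
    m <- classification_metrics(tp, tn, fp, fn)
    expect_equal(m$accuracy, 100 * (tp + tn) / sum(cc))
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    expect_equal(m$mcc, if (denom == 0) 0 else (tp * tn - fp * fn) / denom)
    expect_equal(m$f1, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("rank-sum AUROC matches worked examples and handles ties", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("rank-sum AUROC equals trapezoidal ROC area, with and without ties", {
  set.seed(505)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- if (i %% 2 == 0) {
      round(runif(n), 1) # heavy ties
    } else {
      runif(n)
    }
    expect_equal(auroc(truth, scores), trapezoid_auroc(truth, scores),
                 tolerance = 1e-9)
  }
})

test_that("rank-sum AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(506)
  truth <- rbinom(200, 1, 0.5)
  truth[1:2] <- c(0, 1)
  scores <- runif(200) + truth * 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(truth, scores), ref, tolerance = 1e-9)
})

test_that("split plan is stratified, disjoint, and near-20% per class", {
  d <- simulate_peptides(n_positive = 503, n_negative = 503, seed = 9)
  plan <- make_split(d, seed = 1)
  expect_length(plan$validation_ids, 202) # round(0.2 * 503) per class
  expect_length(plan$train_ids, 804)
  expect_length(intersect(plan$train_ids, plan$validation_ids), 0)
  expect_setequal(unlist(plan$folds), plan$train_ids)
  # per-class fold sizes differ by at most one
  lab <- setNames(d$label, d$id)
  for (cls in c("positive", "negative")) {
    sizes <- sapply(plan$folds, function(f) sum(lab[f] == cls))
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("splits are deterministic in the seed", {
  d <- simulate_peptides(n_positive = 40, n_negative = 40, seed = 3)
  expect_identical(make_split(d, 7), make_split(d, 7))
  expect_false(identical(make_split(d, 7)$validation_ids,
                         make_split(d, 8)$validation_ids))
  # divisible case: five equal folds
  d800 <- simulate_peptides(n_positive = 500, n_negative = 500, seed = 4)
  plan <- make_split(d800, 2)
  expect_equal(lengths(plan$folds), rep(160L, 5))
  expect_error(make_split(d[1:6, ], 1), "at least")
})

test_that("split invariants hold across many random datasets", {
  set.seed(606)
  for (i in 1:100) {
    np <- sample(10:60, 1)
    nn <- sample(10:60, 1)
    d <- peptide_tbl(
      sapply(1:(np + nn), function(i) random_peptide()),
      label = rep(c(1, 0), c(np, nn))
    )
    plan <- make_split(d, seed = i)
    expect_length(intersect(plan$train_ids, plan$validation_ids), 0)
    expect_setequal(c(plan$train_ids, plan$validation_ids), d$id)
    expect_setequal(unlist(plan$folds), plan$train_ids)
    expect_equal(sum(lengths(plan$folds)), length(plan$train_ids))
    lab <- setNames(d$label, d$id)
    for (cls in c("positive", "negative")) {
      expect_equal(sum(lab[plan$validation_ids] == cls),
                   round(0.2 * sum(lab == cls)))
      sizes <- sapply(plan$folds, function(f) sum(lab[f] == cls))
      expect_lte(diff(range(sizes)), 1)
    }
  }
})
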