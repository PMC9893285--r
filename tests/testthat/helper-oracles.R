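# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal possible algorithms.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(min_len = 9, max_len = 20, prob = NULL) {
  L <- if (min_len == max_len) min_len else sample(min_len:max_len, 1)
  paste(sample(AAS, L, replace = TRUE, prob = prob), collapse = "")
}

# every substring of length w, counted character by character
brute_pq_profile <- function(sequence, w) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  sapply(1:(L - w + 1), function(i) {
    win <- chars[i:(i + w - 1)]
    sum(win == "P" | win == "Q") / w
  })
}

# trapezoidal ROC integration from explicit (FPR, TPR) points
trapezoid_auroc <- function(truth, scores) {
  ts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(sapply(ts, function(t) {
    pred <- as.integer(scores >= t)
    c(
      fpr = sum(pred == 1 & truth == 0) / sum(truth == 0),
      tpr = sum(pred == 1 & truth == 1) / sum(truth == 1)
    )
  }))
  sum(diff(pts[, "fpr"]) * (head(pts[, "tpr"], -1) + pts[-1, "tpr"]) / 2)
}

# literal enumeration + filtering + substring-dominance redundancy removal
brute_discover <- function(pos, neg, kmin, kmax, min_positive, max_negative) {
  all_subs <- unique(unlist(lapply(pos, function(s) {
    L <- nchar(s)
    unlist(lapply(kmin:min(kmax, L), function(k) {
      if (k > L) return(character())
      sapply(1:(L - k + 1), function(i) substr(s, i, i + k - 1))
    }))
  })))
  n_pos <- sapply(all_subs, function(p) sum(grepl(p, pos, fixed = TRUE)))
  n_neg <- sapply(all_subs, function(p) sum(grepl(p, neg, fixed = TRUE)))
  keep <- n_pos >= min_positive & n_neg <= max_negative
  pat <- all_subs[keep]; np <- n_pos[keep]; nn <- n_neg[keep]
  covers <- lapply(pat, function(p) which(grepl(p, pos, fixed = TRUE)))
  redundant <- sapply(seq_along(pat), function(i) {
    any(sapply(seq_along(pat), function(j) {
      j != i && nchar(pat[j]) < nchar(pat[i]) &&
        grepl(pat[j], pat[i], fixed = TRUE) &&
        all(covers[[i]] %in% covers[[j]])
    }))
  })
  if (length(pat) == 0) {
    return(data.frame(pattern = character(), positive_count = integer(),
                      negative_count = integer()))
  }
  out <- data.frame(
    pattern = pat[!redundant],
    positive_count = as.integer(np[!redundant]),
    negative_count = as.integer(nn[!redundant]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$positive_count, out$pattern), ]
  rownames(out) <- NULL
  out
}

# per-position naive substring comparison
naive_scan <- function(sequence, patterns) {
  hits <- do.call(rbind, lapply(patterns, function(p) {
    k <- nchar(p)
    starts <- Filter(
      function(i) substr(sequence, i, i + k - 1) == p,
      seq_len(max(0, nchar(sequence) - k + 1))
    )
    if (length(starts) == 0) return(NULL)
    data.frame(motif = p, start = unlist(starts))
  }))
  if (is.null(hits)) data.frame(motif = character(), start = integer()) else
    hits[order(hits$start, hits$motif), ]
}
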