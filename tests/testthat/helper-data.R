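# The default synthetic study dataset (500 + 500, seed 42) is used by
# several end-to-end tests; generate it once per run.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_peptides(n_positive = 500, n_negative = 500, seed = 42)
    }
    cache
  }
})

# a small perfectly separable dataset: all-P positives vs all-A negatives
# (with benign length variation to keep sequences unique)
separable_data <- function(n = 30) {
  peptide_tbl(
    c(
      paste0(strrep("P", 9), strrep("P", seq_len(n) %% 10)),
      paste0(strrep("A", 9), strrep("A", seq_len(n) %% 10))
    ),
    id = c(paste0("p", 1:n), paste0("n", 1:n)),
    label = rep(c(1, 0), each = n)
  )
}
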