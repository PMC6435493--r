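# Shared fixtures, built in code.

# small counts table: n samples x k features, reproducible
toy_counts <- function(n = 4L, k = 3L, seed = 1L, max_count = 20L) {
  set.seed(seed)
  m <- matrix(sample.int(max_count, n * k, replace = TRUE), n, k)
  abundance_table(m, mode = "counts",
                  sample_ids = paste0("S", seq_len(n)),
                  feature_ids = paste0("F", seq_len(k)))
}

# contiguous habitat blocks over a table's samples (first half A, ...)
toy_habitats <- function(x, labels = c("A", "B")) {
  n <- nrow(x)
  stats::setNames(rep(labels, each = ceiling(n / length(labels)))[seq_len(n)],
                  rownames(x))
}

# naive double-loop transcription of the within-habitat centering formula,
# kept deliberately independent of the vectorized implementation
hf_correct_naive <- function(values, habitats) {
  out <- values
  for (i in seq_len(nrow(values))) {
    H <- which(habitats == habitats[i])
    for (j in seq_len(ncol(values))) {
      out[i, j] <- values[i, j] - sum(values[H, j]) / length(H)
    }
  }
  out
}

# two-habitat assignment split in halves
half_habitats <- function(n) {
  stats::setNames(rep(c("A", "B"), each = n / 2), paste0("S", seq_len(n)))
}
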