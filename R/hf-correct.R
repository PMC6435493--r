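#' Habitat-filtering correction by within-habitat mean centering
#'
#' Removes habitat-filtering (HF) effects from an abundance matrix before
#' correlation detection: for every feature, the mean abundance of that
#' feature over the samples of each habitat is subtracted from the feature's
#' values in those samples,
#' \deqn{C_{ij} = A_{ij} - \frac{1}{n}\sum_{k \in H_i} A_{kj},}
#' where \eqn{H_i} is the set of samples sharing sample \eqn{i}'s habitat and
#' \eqn{n = |H_i|}. Between-habitat mean shifts — the signature of habitat
#' filtering — are removed exactly, while within-habitat covariation is
#' untouched, so correlations computed on the corrected matrix reflect
#' associations within habitats rather than shared habitat preference.
#'
#' The correction operates on whatever scale it is given; for real
#' compositional data the recommended order is [clr_transform()] first, then
#' `hf_correct`, then [correlate()].
#'
#' @param x an `abundance_table` or plain numeric matrix
#'   (samples x features).
#' @param habitats habitat assignment: named character vector
#'   (labels named by sample id, see [read_habitat_map()]) or a two-column
#'   data frame. Every sample in `x` must be assigned.
#' @return an `abundance_table` in transformed mode with the same shape and
#'   ids; each feature's mean within each habitat is exactly zero. A habitat
#'   with a single sample triggers a warning (its corrected values are
#'   identically zero).
#' @examples
#' x <- abundance_table(matrix(c(2, 4, 1, 3), 4, 1), mode = "counts")
#' h <- c(S1 = "A", S2 = "A", S3 = "B", S4 = "B")
#' hf_correct(x, h) # -1, 1, -1, 1
#' @export
hf_correct <- function(x, habitats) {
  if (!inherits(x, "abundance_table")) x <- abundance_table(x, mode = "transformed")
  habitats <- as_habitat_map(habitats, x)
  v <- table_values(x)
  sizes <- table(habitats)
  if (any(sizes == 1L))
    warning("habitat(s) with a single sample: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "),
            " (corrected values there are identically 0)")
  out <- v
  for (h in unique(habitats)) {
    rows <- which(habitats == h)
    mu <- colMeans(v[rows, , drop = FALSE])
    out[rows, ] <- sweep(v[rows, , drop = FALSE], 2L, mu)
  }
  abundance_table(out, mode = "transformed")
}
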