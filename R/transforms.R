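#' Rarefy a count table to even depth
#'
#' Randomly subsamples each sample's reads without replacement down to a
#' common depth, the standard normalization for uneven sequencing effort.
#'
#' @param x an `abundance_table` in counts mode with integer counts.
#' @param depth target reads per sample; every sample must have at least
#'   this many (drop shallower samples first).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return an `abundance_table` (counts) whose rows each sum to `depth`.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  if (table_mode(x) != "counts") stop("rarefy requires a counts-mode table")
  v <- table_values(x)
  if (any(v != round(v))) stop("rarefy requires integer counts")
  if (depth < 1) stop("depth must be a positive integer")
  totals <- rowSums(v)
  short <- totals < depth
  if (any(short))
    stop("samples below rarefaction depth ", depth, ": ",
         paste(rownames(v)[short], collapse = ", "))
  out <- with_seed(seed, vegan::rrarefy(v, depth))
  abundance_table(out, mode = "counts")
}

#' Filter features by prevalence
#'
#' Keeps features detected (value strictly greater than zero) in at least a
#' given fraction of samples; the boundary is inclusive.
#'
#' @param x an `abundance_table`.
#' @param min_fraction minimum fraction of samples with the feature present,
#'   in `[0, 1]`.
#' @return the filtered `abundance_table`, feature order preserved.
#' @export
prevalence_filter <- function(x, min_fraction = 0.5) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must be in [0, 1]")
  v <- table_values(x)
  prev <- colMeans(v > 0)
  keep <- prev >= min_fraction
  if (!any(keep))
    stop("prevalence filter removed every feature; lower min_fraction (",
         min_fraction, ")")
  abundance_table(v[, keep, drop = FALSE], mode = table_mode(x))
}

#' Close a count table to relative abundances
#'
#' @param x an `abundance_table` with non-negative values.
#' @return an `abundance_table` in relative mode; each row sums to 1.
#' @export
relative_abundance <- function(x) {
  v <- table_values(x)
  if (any(v < 0)) stop("relative_abundance requires non-negative values")
  totals <- rowSums(v)
  if (any(totals == 0))
    stop("zero-sum samples: ",
         paste(rownames(v)[totals == 0], collapse = ", "))
  abundance_table(v / totals, mode = "relative")
}

#' Centered log-ratio transform
#'
#' Per sample, replaces each value by its log minus the mean log across
#' features, the standard transform for compositional sequence data. Zeros
#' must be handled by a pseudocount; the default of 1 is intended for count
#' scale data (it is added before any closure implied by the caller).
#'
#' @param x an `abundance_table`.
#' @param pseudocount non-negative value added to every entry before taking
#'   logs. With zeros present the pseudocount must be positive.
#' @return an `abundance_table` in transformed mode; rows sum to 0.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  v <- table_values(x) + pseudocount
  if (any(v <= 0))
    stop("zero or negative values remain; set a positive pseudocount")
  lv <- log(v)
  out <- lv - rowMeans(lv)
  abundance_table(out, mode = "transformed")
}
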