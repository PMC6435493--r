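# Scoring of detected networks against simulation truth, and
# habitat-preference bias diagnostics for real-data networks.

#' RMSE between a detected and a true correlation matrix
#'
#' Root mean squared error over the strict upper triangle of the difference
#' between the detected correlation matrix and the true one. Undefined
#' detected correlations (constant features) are scored as 0.
#'
#' @param detected a [correlate()] result or a correlation matrix.
#' @param truth_R true correlation matrix of matching dimension.
#' @return non-negative scalar.
#' @export
correlation_rmse <- function(detected, truth_R) {
  r <- if (inherits(detected, "correlation_result")) detected$r
       else as.matrix(detected)
  truth_R <- as.matrix(truth_R)
  if (!all(dim(r) == dim(truth_R)))
    stop("dimension mismatch: detected ", nrow(r), "x", ncol(r),
         " vs truth ", nrow(truth_R), "x", ncol(truth_R))
  r[is.na(r)] <- 0
  d <- (r - truth_R)[upper.tri(r)]
  sqrt(mean(d^2))
}

#' Proportion of detected network edges that are correct
#'
#' An edge is correct when the pair is truly correlated in the design and
#' the detected sign matches; edges on truly uncorrelated pairs or with the
#' wrong sign are incorrect.
#'
#' @param net a `microbial_network` built with the benchmark cutoff
#'   (p < 0.01, both signs).
#' @param truth_T the \{-1, 0, +1\} design matrix.
#' @return fraction in `[0, 1]`, or `NA` for an edgeless network.
#' @export
proportion_correct <- function(net, truth_T) {
  stopifnot(inherits(net, "microbial_network"))
  truth_T <- as.matrix(truth_T)
  e <- net$edges
  if (nrow(e) == 0L) return(NA_real_)
  ids <- net$nodes$id
  i <- match(e$from, ids); j <- match(e$to, ids)
  true_sign <- truth_T[cbind(i, j)]
  mean(true_sign != 0 & sign(e$r) == true_sign)
}

#' Label features by habitat preference
#'
#' For every feature and every habitat pair, a two-sided Wilcoxon rank-sum
#' test compares abundances between the two habitats; p-values are
#' Benjamini-Hochberg adjusted across all (feature x pair) tests. A feature
#' is labeled as preferring a habitat when it is significantly more abundant
#' there than in every other habitat (adjusted p <= `alpha`, with the
#' rank-sum statistic favoring that habitat). This is a nonparametric
#' stand-in for a full differential-abundance model and makes no claim of
#' equivalence to negative-binomial methods.
#'
#' @param x an `abundance_table`.
#' @param habitats habitat assignments (named vector or data frame);
#'   at least 2 habitats with at least 3 samples each.
#' @param alpha adjusted-p significance level (default 0.05).
#' @return named list: per feature, a character vector of preferred habitats
#'   (empty when no preference).
#' @export
assign_habitat_preference <- function(x, habitats, alpha = 0.05) {
  habitats <- as_habitat_map(habitats, x)
  v <- table_values(x)
  labs <- sort(unique(habitats))
  if (length(labs) < 2L) stop("need at least 2 habitats")
  sizes <- table(habitats)
  if (any(sizes < 3L))
    stop("habitat(s) with fewer than 3 samples: ",
         paste(names(sizes)[sizes < 3L], collapse = ", "))
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  tests <- expand.grid(feature = colnames(v), pair = seq_along(pairs),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(tests)), function(k) {
    j <- tests$feature[k]
    pr <- pairs[[tests$pair[k]]]
    a <- v[habitats == pr[1L], j]; b <- v[habitats == pr[2L], j]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    # W counts pairs where a > b (ties half); > null mean means a larger
    list(p = wt$p.value, greater = if (unname(wt$statistic) >
           length(a) * length(b) / 2) pr[1L] else pr[2L],
         pair = pr)
  })
  p_adj <- stats::p.adjust(vapply(res, `[[`, 0, "p"), method = "BH")
  out <- stats::setNames(vector("list", ncol(v)), colnames(v))
  for (j in colnames(v)) out[[j]] <- character(0)
  for (h in labs) {
    others <- setdiff(labs, h)
    for (j in colnames(v)) {
      rows <- which(tests$feature == j &
                    vapply(tests$pair, function(pi) h %in% pairs[[pi]], TRUE))
      wins <- vapply(rows, function(k)
        !is.na(p_adj[k]) && p_adj[k] <= alpha && res[[k]]$greater == h, TRUE)
      if (length(rows) == length(others) && all(wins))
        out[[j]] <- c(out[[j]], h)
    }
  }
  out
}

#' Write/read habitat-preference labels
#'
#' Two-column TSV: feature id, comma-separated habitat labels (empty field
#' for no preference).
#' @param labels named list of character vectors.
#' @param path file path.
#' @export
write_preference_labels <- function(labels, path) {
  utils::write.table(
    data.frame(feature_id = names(labels),
               preference = vapply(labels, paste, "", collapse = ","),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_preference_labels
#' @export
read_preference_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = NULL)
  out <- lapply(df[[2L]], function(s) {
    s <- as.character(s)
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",")[[1L]]
  })
  stats::setNames(out, df[[1L]])
}

#' Proportion of edges joining nodes with a shared habitat preference
#'
#' The residual habitat-filtering bias measure: the fraction of network
#' edges whose two endpoints have overlapping preference-label sets. Edges
#' touching an unlabeled node count in the denominator but never as shared.
#'
#' @param net a `microbial_network`.
#' @param labels named list of preference label vectors (see
#'   [assign_habitat_preference()]).
#' @return list with `k` (shared edges), `m` (total edges), `proportion`
#'   (`k/m`, `NA` for an empty network).
#' @export
shared_preference_proportion <- function(net, labels) {
  stopifnot(inherits(net, "microbial_network"))
  e <- net$edges
  m <- nrow(e)
  if (m == 0L) return(list(k = 0L, m = 0L, proportion = NA_real_))
  shared <- vapply(seq_len(m), function(k) {
    a <- labels[[e$from[k]]]; b <- labels[[e$to[k]]]
    length(a) > 0L && length(b) > 0L && length(intersect(a, b)) > 0L
  }, TRUE)
  list(k = sum(shared), m = m, proportion = sum(shared) / m)
}

#' Shared-preference proportion expected in a random network
#'
#' Baseline for [shared_preference_proportion()]: `analytic` returns the
#' probability that a uniformly random node pair shares a preference (the
#' count of label-sharing pairs over all pairs); `montecarlo` averages the
#' shared proportion over random graphs with `n_edges` edges.
#'
#' @param labels named list of preference label vectors.
#' @param node_ids nodes to draw pairs from (default: names of `labels`).
#' @param mode `"analytic"` (default) or `"montecarlo"`.
#' @param n_edges edges per random graph (montecarlo only).
#' @param reps number of random graphs (montecarlo only).
#' @param seed integer seed (montecarlo only).
#' @return scalar proportion.
#' @export
random_baseline_proportion <- function(labels, node_ids = names(labels),
                                       mode = c("analytic", "montecarlo"),
                                       n_edges = NULL, reps = 1000L,
                                       seed = 1L) {
  mode <- match.arg(mode)
  n <- length(node_ids)
  if (n < 2L) stop("need at least 2 nodes")
  pair_idx <- utils::combn(n, 2L)
  shares <- vapply(seq_len(ncol(pair_idx)), function(k) {
    a <- labels[[node_ids[pair_idx[1L, k]]]]
    b <- labels[[node_ids[pair_idx[2L, k]]]]
    !is.null(a) && !is.null(b) && length(a) > 0L && length(b) > 0L &&
      length(intersect(a, b)) > 0L
  }, TRUE)
  if (mode == "analytic") return(mean(shares))
  if (is.null(n_edges)) stop("montecarlo mode needs n_edges")
  if (n_edges > ncol(pair_idx))
    stop("n_edges exceeds the number of possible pairs (",
         ncol(pair_idx), ")")
  with_seed(seed, mean(vapply(seq_len(reps), function(rep)
    mean(shares[sample.int(ncol(pair_idx), n_edges)]), 0)))
}

#' Chi-square test for equality of two proportions
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' shared vs non-shared edge counts from two networks.
#'
#' @param k1,m1 shared and total edge counts for the first network.
#' @param k2,m2 same for the second network.
#' @return list with `statistic` and `p`.
#' @export
proportions_chisq <- function(k1, m1, k2, m2) {
  if (m1 <= 0 || m2 <= 0) stop("totals must be positive")
  if (k1 < 0 || k1 > m1 || k2 < 0 || k2 > m2)
    stop("counts must satisfy 0 <= k <= m")
  tab <- rbind(c(k1, m1 - k1), c(k2, m2 - k2))
  if (any(colSums(tab) == 0))
    stop("degenerate margins: a column of the 2x2 table is all zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Paired comparison of two per-replicate metric vectors
#'
#' Two-sided Wilcoxon signed-rank test on per-replicate differences between
#' two methods scored on the same simulated datasets.
#'
#' @param metric_a,metric_b equal-length numeric vectors (one value per
#'   replicate), length at least 6.
#' @return two-sided p-value; 1 when every difference is zero.
#' @export
compare_methods <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("metric vectors must have equal length")
  ok <- !is.na(metric_a) & !is.na(metric_b)
  a <- metric_a[ok]; b <- metric_b[ok]
  if (length(a) < 6L) stop("need at least 6 paired replicates")
  if (all(a == b)) return(1)
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))$p.value
}

#' Principal coordinate analysis on Bray-Curtis dissimilarities
#'
#' Computes the Bray-Curtis dissimilarity matrix between samples and applies
#' classical metric scaling, the standard ordination for spotting
#' habitat-driven community separation before deciding whether
#' habitat-filtering correction is warranted.
#'
#' @param x an `abundance_table` (relative or counts), at least 3 samples.
#' @param k number of coordinate axes to return (default 2).
#' @return list with `coordinates` (samples x k), `eig` (all eigenvalues)
#'   and `explained` (fraction of positive eigenvalue mass per returned
#'   axis). All-identical samples yield all-zero coordinates.
#' @export
pcoa_braycurtis <- function(x, k = 2L) {
  v <- table_values(x)
  if (nrow(v) < 3L) stop("ordination needs at least 3 samples")
  d <- vegan::vegdist(v, method = "bray")
  k <- min(k, nrow(v) - 1L)
  if (all(d == 0)) {
    coords <- matrix(0, nrow(v), k,
                     dimnames = list(rownames(v), paste0("PCo", seq_len(k))))
    return(list(coordinates = coords, eig = rep(0, nrow(v) - 1L),
                explained = rep(0, k)))
  }
  mds <- stats::cmdscale(d, k = k, eig = TRUE)
  coords <- mds$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos <- sum(pmax(mds$eig, 0))
  list(coordinates = coords, eig = mds$eig,
       explained = pmax(mds$eig[seq_len(ncol(coords))], 0) / pos)
}
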