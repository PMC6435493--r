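#' Pairwise correlation and p-value matrices
#'
#' Computes all pairwise Spearman or Pearson correlations between features
#' (columns) with two-sided p-values from the t approximation
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, applied
#' uniformly at every sample size. Spearman correlations are Pearson
#' correlations of mid-ranks. Constant features have undefined correlation:
#' their entries are recorded as `NA` with p-value 1, so they can never form
#' network edges.
#'
#' @param x an `abundance_table` or numeric matrix, samples x features,
#'   with at least 3 samples and 2 features.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return a `correlation_result`: list with symmetric `r` and `p` matrices
#'   (`r` diagonal 1, `p` diagonal `NA`), `method`, `n_samples` and
#'   `feature_ids`.
#' @export
correlate <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- if (inherits(x, "abundance_table")) table_values(x) else as.matrix(x)
  n <- nrow(v)
  if (n < 3L) stop("correlation needs at least 3 samples, got ", n)
  if (ncol(v) < 2L) stop("correlation needs at least 2 features")
  if (is.null(colnames(v))) colnames(v) <- paste0("F", seq_len(ncol(v)))
  w <- if (method == "spearman") apply(v, 2L, rank) else v
  constant <- apply(w, 2L, function(col) max(col) == min(col))
  r <- suppressWarnings(stats::cor(w))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- ifelse(constant, NA_real_, 1)
  # two-sided p from the t approximation; clamp r^2 away from 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(r)] <- 1
  diag(p) <- NA_real_
  structure(list(r = r, p = p, method = method, n_samples = n,
                 feature_ids = colnames(v)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("correlation_result: %d features, %d samples, method: %s\n",
              length(x$feature_ids), x$n_samples, x$method))
  cat(sprintf("  off-diagonal r: median %.3f, range [%.3f, %.3f], %d undefined\n",
              stats::median(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' Threshold a correlation result into a co-occurrence network
#'
#' An edge joins features i and j when `p < p_max`, and (if set)
#' `|r| > r_min`, and (if `positive_only`) `r > 0`. All cutoffs are strict
#' inequalities. Undefined correlations never form edges. Edge p-values are
#' used raw by default; `adjust = "BH"` applies Benjamini-Hochberg across
#' all feature pairs first.
#'
#' @param corr a [correlate()] result.
#' @param p_max significance cutoff in `(0, 1]` (default 0.01).
#' @param r_min optional correlation-strength cutoff applied to `|r|`.
#' @param positive_only keep only positive correlations.
#' @param labels optional habitat-preference labels for the nodes: named
#'   list (per feature, character vector of preferred habitats) as returned
#'   by [assign_habitat_preference()].
#' @param adjust `"none"` (default) or `"BH"` multiple-testing adjustment of
#'   edge p-values before thresholding.
#' @return a `microbial_network`: list with `nodes` (data frame: id,
#'   preference), `edges` (data frame: from, to, r, p with from < to), and
#'   the construction `meta`data.
#' @export
build_network <- function(corr, p_max = 0.01, r_min = NULL,
                          positive_only = FALSE, labels = NULL,
                          adjust = c("none", "BH")) {
  stopifnot(inherits(corr, "correlation_result"))
  adjust <- match.arg(adjust)
  if (p_max <= 0 || p_max > 1) stop("p_max must be in (0, 1]")
  ids <- corr$feature_ids
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  r <- corr$r[ut]
  p <- corr$p[ut]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(r) & p < p_max
  if (!is.null(r_min)) keep <- keep & abs(r) > r_min
  if (positive_only) keep <- keep & r > 0
  edges <- data.frame(from = ids[ut[keep, 1L]], to = ids[ut[keep, 2L]],
                      r = r[keep], p = p[keep], stringsAsFactors = FALSE)
  pref <- rep(NA_character_, length(ids))
  if (!is.null(labels)) {
    lab <- labels[ids]
    pref <- vapply(lab, function(l)
      if (is.null(l) || length(l) == 0L) NA_character_
      else paste(sort(l), collapse = ","), "")
  }
  structure(list(
    nodes = data.frame(id = ids, preference = pref, stringsAsFactors = FALSE),
    edges = edges,
    meta = list(p_max = p_max, r_min = r_min, positive_only = positive_only,
                adjust = adjust, method = corr$method,
                n_samples = corr$n_samples)),
    class = "microbial_network")
}

#' @export
print.microbial_network <- function(x, ...) {
  cat(sprintf("microbial_network: %d nodes, %d edges (method: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$meta$method))
  cat(sprintf("  cutoffs: p < %g%s%s\n", x$meta$p_max,
              if (!is.null(x$meta$r_min))
                sprintf(", |r| > %g", x$meta$r_min) else "",
              if (isTRUE(x$meta$positive_only)) ", positive only" else ""))
  invisible(x)
}

#' @export
summary.microbial_network <- function(object, ...) {
  e <- object$edges
  cat(sprintf("Network of %d features, %d edges\n",
              nrow(object$nodes), nrow(e)))
  if (nrow(e)) {
    cat(sprintf("  r: range [%.3f, %.3f], %d positive / %d negative\n",
                min(e$r), max(e$r), sum(e$r > 0), sum(e$r < 0)))
    deg <- table(c(e$from, e$to))
    cat(sprintf("  degree: mean %.2f, max %d (%s)\n", mean(deg),
                max(deg), names(deg)[which.max(deg)]))
  }
  labeled <- sum(!is.na(object$nodes$preference))
  if (labeled)
    cat(sprintf("  %d nodes carry habitat-preference labels\n", labeled))
  invisible(object)
}

#' @export
as.data.frame.microbial_network <- function(x, ...) x$edges

#' Convert a network to an igraph object
#' @param net a `microbial_network`.
#' @return an undirected `igraph` graph with `r`, `p` edge attributes and a
#'   `preference` node attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "microbial_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::vertex_attr(g, "preference")[is.na(igraph::V(g)$preference)] <- ""
  g
}

#' @export
plot.microbial_network <- function(x, ...) {
  g <- as_igraph(x)
  pref <- igraph::V(g)$preference
  cols <- if (any(nzchar(pref))) {
    pal <- grDevices::rainbow(length(unique(pref[nzchar(pref)])))
    ifelse(nzchar(pref), pal[match(pref, unique(pref[nzchar(pref)]))], "grey80")
  } else "grey60"
  igraph::plot.igraph(g, vertex.color = cols, vertex.label.cex = 0.6,
                      vertex.size = 6, ...)
  invisible(x)
}

#' Write a network to disk
#'
#' `edge-list` writes a TSV with columns feature_i, feature_j, r, p (header
#' always present, so an empty network yields a header-only file);
#' `graphml` writes GraphML with habitat-preference node attributes.
#'
#' @param net a `microbial_network`.
#' @param path output file path.
#' @param format `"edge-list"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "microbial_network"))
  if (format == "edge-list") {
    e <- net$edges
    colnames(e) <- c("feature_i", "feature_j", "r", "p")
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#' @param path edge-list TSV path.
#' @return data frame with columns feature_i, feature_j, r, p.
#' @export
read_network_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
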