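#' Benchmark correlation-detection methods on a simulation grid
#'
#' For every (HF strength, sample size) cell, generates `n_reps` independent
#' simulated datasets (fresh correlation design and HF assignment per
#' replicate, seeds derived deterministically from `base_seed`), scores each
#' method on the same datasets, and aggregates. Methods: `"spearman"` and
#' `"pearson"` on the raw relative abundances, and `"hf_corrected"` =
#' within-habitat mean centering ([hf_correct()]) followed by Spearman.
#' Scores per replicate: correlation-matrix RMSE against the projected true
#' correlation matrix, and the proportion of correct edges in the
#' p < `p_edge` network (both signs) against the initial design. Cells are
#' also compared pairwise between methods with a paired signed-rank test on
#' the replicate scores.
#'
#' @param hf_strengths numeric vector of HF strengths (multiples of the
#'   abundance standard deviation; the study range is 0-10).
#' @param n_samples_list integer vector of total sample sizes (even; the
#'   study range is 6-60, split equally over 2 habitats).
#' @param n_reps replicates per cell (default 50).
#' @param methods subset of `c("spearman", "pearson", "hf_corrected")`.
#' @param n_features,p_corr,p_hf,sd_log simulation-truth parameters
#'   (defaults: 50 features, 10\% correlated pairs, 10\% HF-affected
#'   features, log-scale sd 0.1).
#' @param p_edge network significance cutoff for proportion-correct
#'   (default 0.01).
#' @param clr apply the centered log-ratio transform (pseudocount 0;
#'   simulated abundances are strictly positive) before correlation
#'   detection (default `FALSE`).
#' @param base_seed integer; the whole grid is reproducible from it.
#' @return a `benchmark_result`: list with `scores` (long data frame:
#'   hf_strength, n_samples, method, replicate, rmse, prop_correct,
#'   n_edges), `summary` (per-cell means/sds and count of edgeless
#'   replicates), `comparisons` (per-cell pairwise signed-rank p-values for
#'   both metrics), and `params`.
#' @export
benchmark_grid <- function(hf_strengths, n_samples_list, n_reps = 50L,
                           methods = c("spearman", "pearson", "hf_corrected"),
                           n_features = 50L, p_corr = 0.1, p_hf = 0.1,
                           sd_log = 0.1, p_edge = 0.01, clr = FALSE,
                           base_seed = 1L) {
  if (!length(hf_strengths) || !length(n_samples_list))
    stop("hf_strengths and n_samples_list must be non-empty")
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (hf in hf_strengths) for (ns in n_samples_list) {
    for (rep in seq_len(n_reps)) {
      seed <- derive_seed(base_seed, "cell", hf, ns, rep)
      truth <- simulation_truth(n_features, p_corr, p_hf, sd_log,
                                seed = derive_seed(seed, "truth"))
      ds <- simulate_dataset(truth, ns, hf_strength = hf,
                             seed = derive_seed(seed, "draw"))
      input <- if (clr) clr_transform(ds$table, pseudocount = 0) else ds$table
      for (method in methods) {
        corr <- switch(method,
          spearman     = correlate(input, "spearman"),
          pearson      = correlate(input, "pearson"),
          hf_corrected = correlate(hf_correct(input, ds$habitats), "spearman"))
        net <- build_network(corr, p_max = p_edge)
        rows[[length(rows) + 1L]] <- data.frame(
          hf_strength = hf, n_samples = ns, method = method,
          replicate = rep,
          rmse = correlation_rmse(corr, truth$R_star),
          prop_correct = proportion_correct(net, truth$T),
          n_edges = nrow(net$edges))
      }
    }
  }
  scores <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(scores, scores[c("method", "n_samples", "hf_strength")],
          drop = TRUE),
    function(d) data.frame(
      hf_strength = d$hf_strength[1L], n_samples = d$n_samples[1L],
      method = d$method[1L],
      rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
      prop_correct_mean = mean(d$prop_correct, na.rm = TRUE),
      prop_correct_sd = stats::sd(d$prop_correct, na.rm = TRUE),
      n_edgeless = sum(is.na(d$prop_correct)))))
  rownames(summary) <- NULL
  comparisons <- NULL
  if (length(methods) > 1L && n_reps >= 6L) {
    cmp_rows <- list()
    for (hf in hf_strengths) for (ns in n_samples_list) {
      cell <- scores[scores$hf_strength == hf & scores$n_samples == ns, ]
      for (pair in utils::combn(methods, 2L, simplify = FALSE)) {
        a <- cell[cell$method == pair[1L], ]
        b <- cell[cell$method == pair[2L], ]
        cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
          hf_strength = hf, n_samples = ns,
          method_a = pair[1L], method_b = pair[2L],
          p_rmse = compare_methods(a$rmse, b$rmse),
          p_prop_correct = compare_methods(a$prop_correct, b$prop_correct))
      }
    }
    comparisons <- do.call(rbind, cmp_rows)
  }
  structure(list(scores = scores, summary = summary,
                 comparisons = comparisons,
                 params = list(hf_strengths = hf_strengths,
                               n_samples_list = n_samples_list,
                               n_reps = n_reps, methods = methods,
                               n_features = n_features, p_corr = p_corr,
                               p_hf = p_hf, sd_log = sd_log,
                               p_edge = p_edge, clr = clr,
                               base_seed = as.integer(base_seed))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "benchmark_result: %d HF strengths x %d sample sizes x %d methods, %d reps\n",
    length(p$hf_strengths), length(p$n_samples_list), length(p$methods),
    p$n_reps))
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
summary.benchmark_result <- function(object, ...) object$summary
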