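# Simulator for relative-abundance data with known correlation structure and
# a tunable habitat-filtering effect across two equal-sized habitats.

#' Sample a true correlation design
#'
#' Each unordered feature pair is independently declared perfectly
#' correlated with probability `p_corr`, with a fair coin for the sign;
#' all other pairs are uncorrelated.
#'
#' @param n_features number of features (default 50).
#' @param p_corr probability a pair is correlated (default 0.1).
#' @param seed integer seed.
#' @return symmetric integer matrix in \{-1, 0, +1\} with zero diagonal.
#' @export
sample_true_correlations <- function(n_features = 50L, p_corr = 0.1,
                                     seed = 1L) {
  if (n_features < 2L) stop("need at least 2 features")
  if (p_corr < 0 || p_corr > 1) stop("p_corr must be in [0, 1]")
  n_pairs <- n_features * (n_features - 1L) / 2L
  vals <- with_seed(seed, {
    on <- stats::runif(n_pairs) < p_corr
    sign <- ifelse(stats::runif(n_pairs) < 0.5, 1L, -1L)
    ifelse(on, sign, 0L)
  })
  T <- matrix(0L, n_features, n_features)
  T[upper.tri(T)] <- vals
  T <- T + t(T)
  dimnames(T) <- list(paste0("F", seq_len(n_features)),
                      paste0("F", seq_len(n_features)))
  T
}

#' Nearest valid covariance matrix
#'
#' A +/-1/0 correlation design is generally inconsistent (e.g. A~B and B~C
#' perfectly correlated but A~C not), so it is projected to the nearest
#' (Frobenius) valid correlation matrix with unit diagonal — via the
#' alternating-projections nearest-correlation-matrix computation in
#' [Matrix::nearPD()] with eigenvalue clipping at zero — and then scaled to
#' a covariance with every standard deviation equal to `sd`.
#'
#' @param T symmetric design matrix; its diagonal is treated as 1.
#' @param sd per-feature standard deviation on the log scale (default 0.1).
#' @return list with `Sigma` (`sd^2 * R_star`) and `R_star` (the projected
#'   correlation matrix, PSD within 1e-8).
#' @export
nearest_valid_covariance <- function(T, sd = 0.1) {
  T <- as.matrix(T)
  if (!isSymmetric(unname(T))) stop("design matrix must be symmetric")
  diag(T) <- 1
  proj <- tryCatch(
    Matrix::nearPD(T, corr = TRUE, eig.tol = 1e-8, conv.tol = 1e-10,
                   posd.tol = 0, maxit = 500L),
    error = function(e) stop("nearest-correlation projection failed: ",
                             conditionMessage(e)))
  if (!proj$converged)
    stop("nearest-correlation projection did not converge after ",
         proj$iterations, " iterations")
  R_star <- as.matrix(proj$mat)
  dimnames(R_star) <- dimnames(T)
  if (min(eigen(R_star, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("projected matrix is not PSD within tolerance")
  list(Sigma = sd^2 * R_star, R_star = R_star)
}

#' Sample per-feature habitat-filtering assignments
#'
#' Each feature independently exhibits habitat filtering with probability
#' `p_hf`; affected features prefer habitat B (+1) or habitat A (-1) with
#' equal probability.
#'
#' @param n_features number of features.
#' @param p_hf probability a feature is HF-affected (default 0.1).
#' @param seed integer seed.
#' @return integer vector in \{-1, 0, +1\} of length `n_features`.
#' @export
sample_hf_assignment <- function(n_features, p_hf = 0.1, seed = 1L) {
  if (p_hf < 0 || p_hf > 1) stop("p_hf must be in [0, 1]")
  with_seed(seed, {
    on <- stats::runif(n_features) < p_hf
    sign <- ifelse(stats::runif(n_features) < 0.5, 1L, -1L)
    ifelse(on, sign, 0L)
  })
}

#' Draw a complete simulation truth
#'
#' Bundles the correlation design, its nearest-valid-covariance projection,
#' and the habitat-filtering assignment for one simulated community.
#'
#' @param n_features number of features (default 50).
#' @param p_corr pairwise correlation probability (default 0.1).
#' @param p_hf per-feature HF probability (default 0.1).
#' @param sd_log log-scale standard deviation (default 0.1).
#' @param seed integer seed (design and assignment use derived sub-seeds).
#' @return a `simulation_truth`: list with `T`, `Sigma`, `R_star`,
#'   `hf_assignment` and `params`.
#' @export
simulation_truth <- function(n_features = 50L, p_corr = 0.1, p_hf = 0.1,
                             sd_log = 0.1, seed = 1L) {
  T <- sample_true_correlations(n_features, p_corr,
                                seed = derive_seed(seed, "design"))
  cov <- nearest_valid_covariance(T, sd = sd_log)
  hf <- sample_hf_assignment(n_features, p_hf,
                             seed = derive_seed(seed, "hf"))
  structure(list(T = T, Sigma = cov$Sigma, R_star = cov$R_star,
                 hf_assignment = hf,
                 params = list(n_features = n_features, p_corr = p_corr,
                               p_hf = p_hf, sd_log = sd_log, seed = seed)),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "simulation_truth: %d features, %d correlated pairs, %d HF-affected\n",
    p$n_features, sum(x$T[upper.tri(x$T)] != 0), sum(x$hf_assignment != 0)))
  cat(sprintf("  p_corr %.2f, p_hf %.2f, log-scale sd %.2f, seed %d\n",
              p$p_corr, p$p_hf, p$sd_log, p$seed))
  invisible(x)
}

#' Simulate a relative-abundance dataset with habitat filtering
#'
#' Draws `n_samples` log-scale vectors from a multivariate normal with the
#' truth's covariance and exponentiates them to lognormal abundances. Samples
#' are split evenly between habitats A and B. Each HF-affected feature then
#' receives a habitat shift of `hf_strength` times its own empirical
#' abundance standard deviation, added (on the abundance scale by default)
#' to every sample of its preferred habitat — habitat B for assignment +1,
#' habitat A for -1. Finally each sample is closed to relative abundances,
#' so the habitat effect propagates into the observed compositions.
#'
#' @param truth a [simulation_truth()].
#' @param n_samples even number of samples (half per habitat).
#' @param hf_strength habitat shift in multiples of the per-feature
#'   abundance standard deviation (0 disables the effect; the benchmark
#'   range is 0-10).
#' @param seed integer seed for the normal draws.
#' @param scale `"abundance"` (default) applies the shift after
#'   exponentiation, which keeps abundances non-negative; `"log"` applies
#'   `hf_strength` times the log-scale sd before exponentiation.
#' @return a `simulated_dataset`: list with `table` (relative
#'   `abundance_table`), `habitats` (named vector, "A"/"B"), `raw` (pre-
#'   closure abundance matrix), `truth`, `hf_strength`, `scale`, `seed`.
#' @export
simulate_dataset <- function(truth, n_samples, hf_strength = 0, seed = 1L,
                             scale = c("abundance", "log")) {
  stopifnot(inherits(truth, "simulation_truth"))
  scale <- match.arg(scale)
  if (n_samples %% 2L != 0L)
    stop("n_samples must be even (equal habitat sizes), got ", n_samples)
  if (hf_strength < 0) stop("hf_strength must be non-negative")
  k <- truth$params$n_features
  z <- with_seed(seed,
                 MASS::mvrnorm(n_samples, mu = rep(0, k), Sigma = truth$Sigma))
  z <- matrix(z, nrow = n_samples) # guard the n_samples = 1 drop
  habitats <- stats::setNames(rep(c("A", "B"), each = n_samples / 2L),
                              paste0("S", seq_len(n_samples)))
  hf <- truth$hf_assignment
  if (scale == "log" && hf_strength > 0) {
    sd_log <- truth$params$sd_log
    for (j in which(hf != 0L)) {
      pref <- if (hf[j] > 0L) "B" else "A"
      z[habitats == pref, j] <- z[habitats == pref, j] + hf_strength * sd_log
    }
  }
  abund <- exp(z)
  if (scale == "abundance" && hf_strength > 0) {
    s <- apply(abund, 2L, stats::sd)
    for (j in which(hf != 0L)) {
      pref <- if (hf[j] > 0L) "B" else "A"
      abund[habitats == pref, j] <- abund[habitats == pref, j] +
        hf_strength * s[j]
    }
  }
  dimnames(abund) <- list(names(habitats), colnames(truth$T))
  rel <- abundance_table(abund / rowSums(abund), mode = "relative")
  structure(list(table = rel, habitats = habitats, raw = abund,
                 truth = truth, hf_strength = hf_strength, scale = scale,
                 seed = as.integer(seed)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d samples x %d features, HF strength %g (%s scale), seed %d\n",
    nrow(x$table), ncol(x$table), x$hf_strength, x$scale, x$seed))
  cat(sprintf("  habitats: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$habitats)),
                            table(x$habitats)), collapse = ", ")))
  invisible(x)
}
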