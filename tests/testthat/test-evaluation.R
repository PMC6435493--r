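make_net <- function(edges, ids) {
  structure(list(
    nodes = data.frame(id = ids, preference = NA_character_),
    edges = edges,
    meta = list(p_max = 0.01, r_min = NULL, positive_only = FALSE,
                method = "spearman", n_samples = NA)),
    class = "microbial_network")
}

test_that("correlation RMSE matches its closed form", {
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.6; R[3, 4] <- R[4, 3] <- -0.2
  expect_identical(correlation_rmse(R, R), 0)
  zero <- diag(4)
  expect_equal(correlation_rmse(zero, R),
               sqrt(mean(R[upper.tri(R)]^2)))
  # upper-triangle computation equals full off-diagonal by symmetry
  D <- (zero - R)[row(R) != col(R)]
  expect_equal(correlation_rmse(zero, R), sqrt(mean(D^2)))
  # undefined detected entries score as zero correlation
  withna <- R; withna[1, 2] <- withna[2, 1] <- NA
  expect_equal(correlation_rmse(withna, R), sqrt(0.6^2 / 6))
  expect_error(correlation_rmse(diag(3), R), "dimension mismatch")
})

test_that("proportion correct counts matching-sign true pairs only", {
  ids <- paste0("F", 1:4)
  Tm <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  Tm[1, 2] <- Tm[2, 1] <- 1L
  Tm[3, 4] <- Tm[4, 3] <- -1L
  perfect <- make_net(data.frame(from = c("F1", "F3"), to = c("F2", "F4"),
                                 r = c(0.8, -0.7), p = 0.001), ids)
  expect_equal(proportion_correct(perfect, Tm), 1)
  half <- make_net(data.frame(from = c("F1", "F1"), to = c("F2", "F3"),
                              r = c(0.8, 0.9), p = 0.001), ids)
  expect_equal(proportion_correct(half, Tm), 0.5)
  # wrong sign on a true pair is incorrect
  flipped <- make_net(data.frame(from = "F3", to = "F4", r = 0.9, p = 0.001),
                      ids)
  expect_equal(proportion_correct(flipped, Tm), 0)
  empty <- make_net(data.frame(from = character(0), to = character(0),
                               r = numeric(0), p = numeric(0)), ids)
  expect_true(is.na(proportion_correct(empty, Tm)))
})

test_that("habitat preference labeling finds strong shifts and nothing else", {
  set.seed(33)
  n <- 30
  habitats <- half_habitats(n)
  sdv <- 0.5
  v <- cbind(Fb = ifelse(habitats == "B", 10 * sdv, 0) + rnorm(n, 5, sdv),
             Fa = ifelse(habitats == "A", 10 * sdv, 0) + rnorm(n, 5, sdv),
             Fn = rnorm(n, 5, sdv))
  rownames(v) <- names(habitats)
  labels <- assign_habitat_preference(abundance_table(v), habitats)
  expect_identical(labels$Fb, "B")
  expect_identical(labels$Fa, "A")
  expect_identical(labels$Fn, character(0))
  tiny <- abundance_table(v[c(1, 2, 16, 17), ])
  tiny_h <- stats::setNames(c("A", "A", "B", "B"), rownames(tiny))
  expect_error(assign_habitat_preference(tiny, tiny_h), "fewer than 3")
  # labels survive a file round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_preference_labels(labels, path)
  expect_identical(read_preference_labels(path), labels)
})

test_that("BH adjustment on equal raw p-values leaves them unchanged", {
  # step-up with all p equal: p * m / m = p at every rank
  p <- rep(0.03, 7)
  expect_equal(stats::p.adjust(p, "BH"), p)
  # and the labeling respects the adjusted threshold: with many pure-noise
  # features alongside one strong signal, only the signal is labeled
  set.seed(44)
  n <- 24
  habitats <- half_habitats(n)
  v <- cbind(sig = ifelse(habitats == "B", 8, 0) + rnorm(n, 5, 0.5),
             matrix(rnorm(n * 10, 5, 0.5), n,
                    dimnames = list(NULL, paste0("N", 1:10))))
  rownames(v) <- names(habitats)
  labels <- assign_habitat_preference(abundance_table(v), habitats)
  expect_identical(labels$sig, "B")
  expect_true(all(lengths(labels[paste0("N", 1:10)]) == 0))
})

test_that("shared-preference proportion enumerates label overlaps", {
  ids <- paste0("F", 1:4)
  labels <- list(F1 = "A", F2 = "A", F3 = "B", F4 = "B")
  net <- make_net(data.frame(from = c("F1", "F1"), to = c("F2", "F3"),
                             r = c(0.9, 0.8), p = 0.001), ids)
  sp <- shared_preference_proportion(net, labels)
  expect_identical(sp$k, 1L)
  expect_identical(sp$m, 2L)
  expect_equal(sp$proportion, 0.5)
  # all nodes sharing one label -> 1.0
  all_a <- lapply(labels, function(x) "A")
  expect_equal(shared_preference_proportion(net, all_a)$proportion, 1)
  # unlabeled endpoint counts in the denominator only
  labels$F2 <- character(0)
  sp2 <- shared_preference_proportion(net, labels)
  expect_identical(sp2$k, 0L)
  expect_identical(sp2$m, 2L)
  # multi-label overlap counts as shared
  labels3 <- list(F1 = c("A", "B"), F2 = "B", F3 = "C", F4 = "C")
  sp3 <- shared_preference_proportion(net, labels3)
  expect_identical(sp3$k, 1L)
  empty <- make_net(data.frame(from = character(0), to = character(0),
                               r = numeric(0), p = numeric(0)), ids)
  expect_true(is.na(shared_preference_proportion(empty, labels)$proportion))
})

test_that("random baseline: analytic pair enumeration and Monte Carlo agree", {
  labels <- list(F1 = "A", F2 = "A", F3 = "B", F4 = "B")
  expect_equal(random_baseline_proportion(labels), 1 / 3)
  none <- list(F1 = character(0), F2 = character(0))
  expect_equal(random_baseline_proportion(none), 0)
  mc <- random_baseline_proportion(labels, mode = "montecarlo",
                                   n_edges = 3, reps = 10000, seed = 2)
  # each graph averages 3 of 6 pairs with share indicator mean 1/3
  se <- sqrt(1 / 3 * 2 / 3 / 3) / sqrt(10000)
  expect_lt(abs(mc - 1 / 3), 3 * se * 3) # conservative: draws not independent
  expect_error(random_baseline_proportion(labels, mode = "montecarlo",
                                          n_edges = 10), "exceeds")
  # complete graph equals the analytic baseline exactly
  net <- make_net(data.frame(from = c("F1", "F1", "F1", "F2", "F2", "F3"),
                             to = c("F2", "F3", "F4", "F3", "F4", "F4"),
                             r = 0.9, p = 0.001), names(labels))
  expect_equal(shared_preference_proportion(net, labels)$proportion,
               random_baseline_proportion(labels))
})

test_that("chi-square equality of proportions matches the hand-computed statistic", {
  out <- proportions_chisq(30, 100, 10, 100)
  expect_equal(out$statistic, 12.5, tolerance = 1e-12)
  expect_equal(out$p, stats::pchisq(12.5, 1, lower.tail = FALSE))
  # equal proportions give statistic 0, p 1
  eq <- proportions_chisq(20, 50, 40, 100)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
  # row swap leaves the statistic unchanged
  swapped <- proportions_chisq(10, 100, 30, 100)
  expect_equal(swapped$statistic, out$statistic)
  expect_error(proportions_chisq(0, 10, 0, 10), "degenerate")
})

test_that("paired method comparison behaves at the edges and under a unit shift", {
  a <- rnorm(50)
  expect_equal(compare_methods(a, a), 1)
  p <- compare_methods(a, a + 1)
  expect_lt(p, 0.001)
  expect_equal(compare_methods(a + 1, a), p) # two-sided symmetry
  expect_error(compare_methods(a[1:3], a[1:3] + 1), "at least 6")
})

test_that("Bray-Curtis PCoA reproduces hand-computed dissimilarities", {
  v <- rbind(S1 = c(0.5, 0.5), S2 = c(0.25, 0.75), S3 = c(0.5, 0.5))
  d <- vegan::vegdist(v, "bray")
  expect_equal(as.matrix(d)["S1", "S2"], 0.25) # sum|x-y| / sum(x+y)
  expect_equal(as.matrix(d)["S1", "S3"], 0)    # duplicated sample
  disjoint <- rbind(S1 = c(1, 0), S2 = c(0, 1), S3 = c(1, 0))
  expect_equal(max(vegan::vegdist(disjoint, "bray")), 1)
  ord <- pcoa_braycurtis(abundance_table(v, mode = "relative"))
  expect_identical(dim(ord$coordinates), c(3L, 2L))
  # duplicated samples land on the same point (absolute tolerance: the
  # second axis is numerically zero)
  expect_lt(max(abs(ord$coordinates["S1", ] - ord$coordinates["S3", ])),
            1e-6)
  # degenerate all-identical input: all-zero coordinates, no error
  same <- abundance_table(rbind(S1 = c(0.5, 0.5), S2 = c(0.5, 0.5),
                                S3 = c(0.5, 0.5)), mode = "relative")
  expect_true(all(pcoa_braycurtis(same)$coordinates == 0))
})
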