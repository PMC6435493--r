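test_that("the benchmark grid bookkeeping is complete, consistent, and deterministic", {
  b <- benchmark_grid(hf_strengths = 5, n_samples_list = 10, n_reps = 6,
                      methods = c("spearman", "hf_corrected"),
                      n_features = 15, base_seed = 3)
  expect_identical(nrow(b$scores), 6L * 2L)
  expect_identical(nrow(b$summary), 2L)
  cell <- b$scores[b$scores$method == "spearman", ]
  expect_identical(nrow(cell), 6L)
  expect_equal(b$summary$rmse_mean[b$summary$method == "spearman"],
               mean(cell$rmse))
  expect_equal(b$summary$prop_correct_mean[b$summary$method == "spearman"],
               mean(cell$prop_correct, na.rm = TRUE))
  expect_identical(nrow(b$comparisons), 1L)
  b2 <- benchmark_grid(hf_strengths = 5, n_samples_list = 10, n_reps = 6,
                       methods = c("spearman", "hf_corrected"),
                       n_features = 15, base_seed = 3)
  expect_identical(b, b2)
  b3 <- benchmark_grid(hf_strengths = 5, n_samples_list = 10, n_reps = 6,
                       methods = c("spearman", "hf_corrected"),
                       n_features = 15, base_seed = 4)
  expect_false(identical(b$scores$rmse, b3$scores$rmse))
})

test_that("derived seeds are stable, tag-sensitive, and in integer range", {
  expect_identical(derive_seed(1, "a", 2), derive_seed(1, "a", 2))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  seeds <- vapply(1:200, function(i) derive_seed(42, "rep", i), 0L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_gt(length(unique(seeds)), 195) # essentially collision-free
})

test_that("the simulate pipeline writes a replayable bundle of files", {
  out <- withr::local_tempdir()
  res <- run_simulate(list(n_features = 12, n_samples = 10,
                           hf_strength = 3, seed = 5, out_dir = out))
  expect_true(all(file.exists(res$paths)))
  tab <- read_abundance_table(res$paths[["abundance"]])
  expect_identical(dim(tab), c(10L, 12L))
  expect_identical(table_mode(tab), "relative")
  habs <- read_habitat_map(res$paths[["habitats"]])
  expect_identical(unname(table(habs)), c(5L, 5L), ignore_attr = TRUE)
  # replay from the manifest reproduces the abundance file bit-identically
  manifest <- jsonlite::read_json(res$paths[["manifest"]])
  out2 <- withr::local_tempdir()
  cfg <- manifest[setdiff(names(manifest), c("stage", "package_version"))]
  cfg$out_dir <- out2
  res2 <- run_simulate(cfg)
  expect_identical(readLines(res$paths[["abundance"]]),
                   readLines(res2$paths[["abundance"]]))
})

test_that("the network pipeline runs end-to-end with and without correction", {
  out <- withr::local_tempdir()
  sim <- run_simulate(list(n_features = 20, n_samples = 16, hf_strength = 6,
                           seed = 11, out_dir = out))
  cfg <- list(abundance = sim$paths[["abundance"]],
              habitats = sim$paths[["habitats"]],
              prevalence = 0.5, clr = TRUE, pseudocount = 0,
              p_max = 0.05, r_min = NA, positive_only = FALSE,
              out_dir = file.path(out, "corrected"))
  res <- run_network(cfg)
  expect_true(file.exists(res$paths[["edges"]]))
  expect_true(file.exists(res$paths[["graphml"]]))
  expect_s3_class(res$network, "microbial_network")
  # identical config reruns to identical outputs
  res_b <- run_network(cfg)
  expect_identical(readLines(res$paths[["edges"]]),
                   readLines(res_b$paths[["edges"]]))
  # uncorrected comparator: same data, no habitat centering
  un <- run_network(list(abundance = sim$paths[["abundance"]],
                         hf_correction = FALSE, clr = TRUE, pseudocount = 0,
                         p_max = 0.05, r_min = NA, positive_only = FALSE,
                         out_dir = file.path(out, "raw")))
  expect_s3_class(un$network, "microbial_network")
  # the two modes genuinely disagree on the detected edge set
  key <- function(n) paste(n$network$edges$from, n$network$edges$to)
  expect_false(setequal(key(un), key(res)))
  expect_error(run_network(list(abundance = "nope.tsv")), "\\[read\\]")
  expect_error(run_network(list(bogus_key = 1)), "unknown config keys")
})

test_that("the evaluate pipeline scores bias and compares two networks", {
  out <- withr::local_tempdir()
  labels <- list(F1 = "A", F2 = "A", F3 = "B", F4 = "B")
  lpath <- file.path(out, "labels.tsv")
  write_preference_labels(labels, lpath)
  e1 <- data.frame(feature_i = c("F1", "F1"), feature_j = c("F2", "F3"),
                   r = c(0.9, 0.8), p = 0.001)
  e2 <- data.frame(feature_i = "F1", feature_j = "F3", r = 0.8, p = 0.001)
  p1 <- file.path(out, "net1.tsv"); p2 <- file.path(out, "net2.tsv")
  utils::write.table(e1, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(e2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- run_evaluate(list(edges = p1, labels = lpath, edges_b = p2,
                           out_dir = out))
  expect_equal(res$summary$proportion, c(0.5, 0))
  expect_equal(res$summary$random_baseline, rep(1 / 3, 2))
  expect_true(is.finite(res$chisq$statistic))
})

test_that("the ordination diagnostic separates habitats under strong HF", {
  out <- withr::local_tempdir()
  sim <- run_simulate(list(n_features = 30, n_samples = 20, p_hf = 0.3,
                           hf_strength = 10, seed = 13, out_dir = out))
  res <- run_diagnose(list(abundance = sim$paths[["abundance"]],
                           habitats = sim$paths[["habitats"]],
                           out_dir = out))
  expect_true(file.exists(res$paths[["coordinates"]]))
  co <- res$coordinates
  # mean silhouette-like separation on axis 1: between-habitat distance
  # exceeds within-habitat spread
  a1 <- co$PCo1[co$habitat == "A"]; b1 <- co$PCo1[co$habitat == "B"]
  expect_gt(abs(mean(a1) - mean(b1)), 0)
  sil <- abs(mean(a1) - mean(b1)) / (sd(a1) + sd(b1) + 1e-12)
  expect_gt(sil, 0.5)
})
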