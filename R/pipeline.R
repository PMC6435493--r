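# End-to-end pipeline runs: each writes tabular outputs plus a JSON
# manifest echoing the fully resolved configuration and seeds, so any run
# can be replayed bit-identically from its manifest.

write_manifest <- function(config, out_dir, stage) {
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(c(list(stage = stage, package_version =
    as.character(utils::packageVersion("hfnet"))), config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

resolve_config <- function(config, defaults) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Run the network-construction pipeline
#'
#' read -> (optional rarefy) -> prevalence filter -> relative abundance ->
#' CLR -> (optional HF correction) -> correlate -> threshold -> write.
#' Defaults mirror a multi-habitat amplicon study: prevalence >= 50\%,
#' CLR with pseudocount 1, HF correction then Spearman, p < 0.01,
#' r > 0.75, positive edges only.
#'
#' @param config named list overriding any of: `abundance` (path, required),
#'   `habitats` (path, required when `hf_correction`), `orientation`,
#'   `delimiter`, `rarefy_depth` (NULL = skip), `prevalence` (0.5),
#'   `pseudocount` (1), `clr` (TRUE), `hf_correction` (TRUE), `method`
#'   ("spearman"), `p_max` (0.01), `r_min` (0.75; NA = none),
#'   `positive_only` (TRUE), `labels` (optional preference-labels path),
#'   `seed` (1), `out_dir` (".").
#' @return invisibly, a list with the `microbial_network` and output paths.
#' @export
run_network <- function(config) {
  cfg <- resolve_config(config, list(
    abundance = NULL, habitats = NULL, orientation = "samples-as-rows",
    delimiter = "\t", rarefy_depth = NULL, prevalence = 0.5,
    pseudocount = 1, clr = TRUE, hf_correction = TRUE, method = "spearman",
    p_max = 0.01, r_min = 0.75, positive_only = TRUE, labels = NULL,
    seed = 1L, out_dir = "."))
  if (is.null(cfg$abundance)) stop("config$abundance (path) is required")
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  x <- stage("read", read_abundance_table(cfg$abundance, cfg$orientation,
                                          cfg$delimiter))
  if (!is.null(cfg$rarefy_depth) && !is.na(cfg$rarefy_depth))
    x <- stage("rarefy", rarefy(x, cfg$rarefy_depth,
                                seed = derive_seed(cfg$seed, "rarefy")))
  x <- stage("prevalence_filter", prevalence_filter(x, cfg$prevalence))
  if (table_mode(x) == "counts")
    x <- stage("relative_abundance", relative_abundance(x))
  if (isTRUE(cfg$clr))
    x <- stage("clr_transform", clr_transform(x, cfg$pseudocount))
  habitats <- NULL
  if (isTRUE(cfg$hf_correction)) {
    if (is.null(cfg$habitats))
      stop("[hf_correct] config$habitats (path) is required")
    habitats <- stage("read_habitat_map", read_habitat_map(cfg$habitats))
    x <- stage("hf_correct", hf_correct(x, habitats))
  }
  corr <- stage("correlate", correlate(x, cfg$method))
  labels <- if (!is.null(cfg$labels))
    stage("read_labels", read_preference_labels(cfg$labels)) else NULL
  r_min <- if (is.null(cfg$r_min) || is.na(cfg$r_min)) NULL else cfg$r_min
  net <- stage("build_network",
               build_network(corr, p_max = cfg$p_max, r_min = r_min,
                             positive_only = isTRUE(cfg$positive_only),
                             labels = labels))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(cfg$out_dir, "network_edges.tsv")
  gml_path <- file.path(cfg$out_dir, "network.graphml")
  write_network(net, edge_path, "edge-list")
  write_network(net, gml_path, "graphml")
  manifest <- write_manifest(cfg, cfg$out_dir, "network")
  invisible(list(network = net,
                 paths = c(edges = edge_path, graphml = gml_path,
                           manifest = manifest)))
}

#' Run the simulator and write its outputs
#'
#' Writes the relative-abundance table, habitat map, truth bundle (design
#' matrix, projected correlation matrix, HF assignment) as TSVs, plus a
#' manifest.
#'
#' @param config named list overriding any of: `n_features` (50), `p_corr`
#'   (0.1), `p_hf` (0.1), `sd_log` (0.1), `n_samples` (30), `hf_strength`
#'   (0), `scale` ("abundance"), `seed` (1), `out_dir` (".").
#' @return invisibly, a list with the `simulated_dataset` and output paths.
#' @export
run_simulate <- function(config = list()) {
  cfg <- resolve_config(config, list(
    n_features = 50L, p_corr = 0.1, p_hf = 0.1, sd_log = 0.1,
    n_samples = 30L, hf_strength = 0, scale = "abundance", seed = 1L,
    out_dir = "."))
  truth <- simulation_truth(cfg$n_features, cfg$p_corr, cfg$p_hf,
                            cfg$sd_log, seed = derive_seed(cfg$seed, "truth"))
  ds <- simulate_dataset(truth, cfg$n_samples, cfg$hf_strength,
                         seed = derive_seed(cfg$seed, "draw"),
                         scale = cfg$scale)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    abundance = file.path(cfg$out_dir, "abundance.tsv"),
    habitats = file.path(cfg$out_dir, "habitats.tsv"),
    design = file.path(cfg$out_dir, "truth_design.tsv"),
    r_star = file.path(cfg$out_dir, "truth_correlation.tsv"),
    hf = file.path(cfg$out_dir, "truth_hf_assignment.tsv"))
  write_abundance_table(ds$table, paths["abundance"])
  write_habitat_map(ds$habitats, paths["habitats"])
  write_named_matrix(truth$T, paths["design"])
  write_named_matrix(truth$R_star, paths["r_star"])
  utils::write.table(
    data.frame(feature_id = colnames(truth$T),
               hf_assignment = truth$hf_assignment),
    paths["hf"], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(cfg, cfg$out_dir, "simulate")
  invisible(list(dataset = ds, paths = c(paths, manifest = manifest)))
}

write_named_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the benchmark grid and write long-format score tables
#'
#' @param config named list overriding any of the [benchmark_grid()]
#'   arguments (`hf_strengths` default `c(0, 5)`, `n_samples_list` default
#'   30, `n_reps` 50, plus `out_dir`, `seed`).
#' @return invisibly, a list with the `benchmark_result` and output paths.
#' @export
run_benchmark <- function(config = list()) {
  cfg <- resolve_config(config, list(
    hf_strengths = c(0, 5), n_samples_list = 30L, n_reps = 50L,
    methods = c("spearman", "pearson", "hf_corrected"), n_features = 50L,
    p_corr = 0.1, p_hf = 0.1, sd_log = 0.1, p_edge = 0.01, clr = FALSE,
    seed = 1L, out_dir = "."))
  bench <- benchmark_grid(cfg$hf_strengths, cfg$n_samples_list, cfg$n_reps,
                          cfg$methods, cfg$n_features, cfg$p_corr, cfg$p_hf,
                          cfg$sd_log, cfg$p_edge, cfg$clr,
                          base_seed = cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scores = file.path(cfg$out_dir, "benchmark_scores.tsv"),
             summary = file.path(cfg$out_dir, "benchmark_summary.tsv"),
             comparisons = file.path(cfg$out_dir,
                                     "benchmark_comparisons.tsv"))
  utils::write.table(bench$scores, paths["scores"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bench$summary, paths["summary"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bench$comparisons))
    utils::write.table(bench$comparisons, paths["comparisons"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(cfg, cfg$out_dir, "benchmark")
  invisible(list(benchmark = bench, paths = c(paths, manifest = manifest)))
}

#' Evaluate habitat-preference bias of one or two networks
#'
#' Computes the shared-preference proportion of a network's edges, the
#' analytic random baseline over its nodes, and — when a second network is
#' given — the chi-square test for equality of the two proportions.
#'
#' @param config named list: `edges` (edge-list TSV path, required),
#'   `labels` (preference-labels TSV path, required), optional `edges_b`
#'   (second network for comparison), `out_dir`.
#' @return invisibly, a list with the bias summary (written as
#'   `bias_summary.tsv`) and, if applicable, the chi-square comparison.
#' @export
run_evaluate <- function(config) {
  cfg <- resolve_config(config, list(edges = NULL, labels = NULL,
                                     edges_b = NULL, out_dir = "."))
  if (is.null(cfg$edges) || is.null(cfg$labels))
    stop("config$edges and config$labels are required")
  labels <- read_preference_labels(cfg$labels)
  net_from_edges <- function(path) {
    e <- read_network_edges(path)
    ids <- sort(unique(c(e$feature_i, e$feature_j, names(labels))))
    structure(list(
      nodes = data.frame(id = ids, preference = NA_character_),
      edges = data.frame(from = e$feature_i, to = e$feature_j,
                         r = e$r, p = e$p),
      meta = list(p_max = NA, r_min = NULL, positive_only = NA,
                  method = "file", n_samples = NA)),
      class = "microbial_network")
  }
  net <- net_from_edges(cfg$edges)
  sp <- shared_preference_proportion(net, labels)
  baseline <- random_baseline_proportion(labels, net$nodes$id)
  rows <- data.frame(network = cfg$edges, shared = sp$k, total = sp$m,
                     proportion = sp$proportion, random_baseline = baseline)
  chisq <- NULL
  if (!is.null(cfg$edges_b)) {
    sp2 <- shared_preference_proportion(net_from_edges(cfg$edges_b), labels)
    rows <- rbind(rows, data.frame(network = cfg$edges_b, shared = sp2$k,
                                   total = sp2$m, proportion = sp2$proportion,
                                   random_baseline = baseline))
    chisq <- proportions_chisq(sp$k, sp$m, sp2$k, sp2$m)
    rows$chisq_statistic <- chisq$statistic
    rows$chisq_p <- chisq$p
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, "bias_summary.tsv")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- write_manifest(cfg, cfg$out_dir, "evaluate")
  invisible(list(summary = rows, chisq = chisq,
                 paths = c(summary = path, manifest = manifest)))
}

#' Ordination diagnostic for habitat effects
#'
#' Bray-Curtis PCoA of the samples with their habitat labels attached — the
#' look-before-you-correct diagnostic: clear habitat separation in the
#' leading coordinates signals habitat filtering.
#'
#' @param config named list: `abundance` (path, required), `habitats`
#'   (path, required), optional `orientation`, `delimiter`, `k` (2),
#'   `out_dir`.
#' @return invisibly, a list with the coordinates data frame (written as
#'   `pcoa_coordinates.tsv`) and explained-variance fractions.
#' @export
run_diagnose <- function(config) {
  cfg <- resolve_config(config, list(abundance = NULL, habitats = NULL,
                                     orientation = "samples-as-rows",
                                     delimiter = "\t", k = 2L,
                                     out_dir = "."))
  if (is.null(cfg$abundance) || is.null(cfg$habitats))
    stop("config$abundance and config$habitats are required")
  x <- read_abundance_table(cfg$abundance, cfg$orientation, cfg$delimiter)
  if (table_mode(x) == "counts") x <- relative_abundance(x)
  habitats <- as_habitat_map(read_habitat_map(cfg$habitats), x)
  ord <- pcoa_braycurtis(x, k = cfg$k)
  df <- data.frame(sample_id = rownames(ord$coordinates),
                   habitat = unname(habitats), ord$coordinates)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, "pcoa_coordinates.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_manifest(cfg, cfg$out_dir, "diagnose")
  invisible(list(coordinates = df, explained = ord$explained,
                 paths = c(coordinates = path, manifest = manifest)))
}
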