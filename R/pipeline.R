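# End-to-end orchestration: one config, deterministic per-stage seeding, a
# run manifest with filter-funnel counts, and all stage outputs written to
# disk in the pipeline's plain-text formats.

#' Default pipeline configuration
#'
#' Every tunable of every stage with its package default; pass overrides as
#' name = value. Unknown names are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `RunConfig`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    # synthetic generation (used when no matrix path is supplied)
    synthetic = TRUE, n_genes = 600, n_conditions = 60,
    effect_size = 2, noise_sd = 1,
    matrix_path = NULL,
    # gene filtering
    min_variance = 0,
    # ISA sweep
    gene_thresholds = seq(2, 4, by = 0.5),
    condition_thresholds = seq(2, 4, by = 0.5),
    n_random_seeds = 100,
    robust_n_shuffles = 2, robust_quantile = 1,
    max_genes = 200, min_intra_correlation = 0.4, unique_threshold = 0.9,
    min_genes = 2, min_conditions = 3,
    # module clustering
    cut_height = 0.5, linkage = "complete",
    # activation / enrichment
    activation_quantile = 0.75, enrichment_adjust = NULL,
    # signature
    signature_k = 30, n_trees = 1001,
    # network nulls
    null_iterations = 1000, swap_rounds = 10,
    hub_threshold = 5, traffic_threshold = 0.09,
    # co-expression frequency
    query_gene = NULL, top_fraction = 0.20, min_count = 3,
    drop_fractions = c(0.05, 0.10),
    # stage toggles
    run_signature = TRUE, run_network = TRUE, run_coexpr = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("RunConfig", "list"))
}

#' Run the whole module-mining pipeline
#'
#' Executes the stages in dependency order: data generation/loading, gene
#' filtering, the ISA threshold sweep-and-merge, overlap clustering into
#' module clusters, Z-score activation and enrichment, the random-forest
#' injury signature, the interaction sub-network significance analysis, and
#' frequent co-expression statistics. A fixed config and seed reproduce the
#' run bit-identically; each stage draws its own seed from the master seed.
#'
#' @param config from [default_config()].
#' @param out_dir directory for stage outputs and the manifest; created if
#'   missing. NULL skips writing.
#' @return list with all in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()
  manifest <- list(config = unclass(config), stages = list(),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"))
  timing <- function(since) as.numeric(Sys.time() - since, units = "secs")

  # --- data -----------------------------------------------------------
  ts <- Sys.time()
  if (config$synthetic) {
    study <- synthetic_study(config$n_genes, config$n_conditions,
                             config$effect_size, config$noise_sd,
                             seed = derive_seed(config$seed, "study"))
  } else {
    if (is.null(config$matrix_path)) stop("matrix_path required")
    study <- list(matrix = read_matrix_tsv(config$matrix_path),
                  metadata = NULL, network = NULL, labels = NULL,
                  target_genes = NULL, truth = NULL)
  }
  mat <- filter_genes(study$matrix, min_variance = config$min_variance)
  manifest$stages$data <- list(n_genes = nrow(mat),
                               n_conditions = ncol(mat),
                               matrix_digest = matrix_digest(mat),
                               seconds = timing(ts))

  # --- ISA sweep ------------------------------------------------------
  ts <- Sys.time()
  modules <- sweep_and_merge(
    mat,
    gene_thresholds = config$gene_thresholds,
    condition_thresholds = config$condition_thresholds,
    n_random_seeds = config$n_random_seeds,
    rng_seed = derive_seed(config$seed, "isa"),
    robust_n_shuffles = config$robust_n_shuffles,
    robust_quantile = config$robust_quantile,
    max_genes = config$max_genes,
    min_intra_correlation = config$min_intra_correlation,
    min_genes = config$min_genes, min_conditions = config$min_conditions,
    unique_threshold = config$unique_threshold)
  manifest$stages$isa <- list(n_modules = length(modules),
                              seconds = timing(ts))
  if (length(modules) < 2L)
    stop("pipeline aborted at stage module_clustering: < 2 modules mined")

  # --- module clustering ---------------------------------------------
  ts <- Sys.time()
  ov <- overlap_matrix(modules)
  clusters <- cluster_modules(ov, modules, cut_height = config$cut_height,
                              linkage = config$linkage)
  manifest$stages$clustering <- list(n_clusters = length(clusters),
                                     seconds = timing(ts))

  # --- activation & enrichment ---------------------------------------
  ts <- Sys.time()
  z <- zscore_matrix(mat)
  phenotypes <- list()
  activation <- NULL
  enrichment <- NULL
  if (!is.null(study$metadata)) {
    hp <- study$metadata$histopath
    for (ph in unique(hp$phenotype))
      phenotypes[[ph]] <- define_phenotype_from_histopath(hp, ph)
    cond_meta <- study$metadata$conditions
    for (cl in stats::na.omit(unique(cond_meta$class)))
      phenotypes[[cl]] <- define_phenotype_from_class(cond_meta, cl)
    phenotypes <- Filter(function(p) length(p$condition_ids) > 0, phenotypes)
    if (length(phenotypes))
      activation <- activation_table(clusters, unname(phenotypes), z)
  }
  if (!is.null(study$target_genes))
    enrichment <- enrich_clusters(clusters, study$target_genes,
                                  universe = rownames(mat),
                                  adjust = config$enrichment_adjust)
  manifest$stages$activation <- list(
    n_phenotypes = length(phenotypes),
    n_clusters_scored = length(clusters), seconds = timing(ts))

  # --- injury signature ----------------------------------------------
  signature <- NULL
  if (config$run_signature && !is.null(study$labels)) {
    ts <- Sys.time()
    candidate_genes <- intersect(study$target_genes %||% rownames(mat),
                                 rownames(mat))
    train <- training_set(mat, study$labels)
    rank_fit <- train_forest(train, feature_subset = candidate_genes,
                             n_trees = config$n_trees,
                             rng_seed = derive_seed(config$seed, "rf_rank"))
    k <- min(config$signature_k, length(candidate_genes))
    sig_genes <- select_signature(rank_fit, k = k)
    final_fit <- train_forest(train, feature_subset = sig_genes,
                              n_trees = config$n_trees,
                              rng_seed = derive_seed(config$seed, "rf_final"))
    perf <- evaluate_signature(final_fit, train)
    signature <- list(genes = sig_genes, model = final_fit,
                      performance = perf, ranking_model = rank_fit)
    manifest$stages$signature <- list(
      k = k, oob_error = final_fit$oob_error, auc = perf$auc,
      sensitivity = perf$sensitivity, specificity = perf$specificity,
      seconds = timing(ts))
  }

  # --- PPI sub-network -------------------------------------------------
  network_stats <- NULL
  if (config$run_network && !is.null(study$network)) {
    ts <- Sys.time()
    genes <- study$target_genes %||% rownames(mat)
    sn <- extract_subnetwork(genes, study$network)
    cs <- centrality_stats(sn, hub_threshold = config$hub_threshold,
                           traffic_threshold = config$traffic_threshold)
    rnd <- random_node_test(study$network, length(genes),
                            igraph::vcount(sn), igraph::ecount(sn),
                            n_iter = config$null_iterations,
                            rng_seed = derive_seed(config$seed, "null_node"))
    dps <- degree_preserving_test(study$network, genes,
                                  n_iter = config$null_iterations,
                                  swap_rounds = config$swap_rounds,
                                  rng_seed = derive_seed(config$seed,
                                                         "null_rewire"))
    network_stats <- list(subnetwork = sn, centrality = cs,
                          random_node = rnd[c("p_nodes", "p_edges")],
                          degree_preserving = dps[c("p_nodes", "p_edges")])
    manifest$stages$network <- list(
      n_nodes = igraph::vcount(sn), n_edges = igraph::ecount(sn),
      p_edges_random = rnd$p_edges, p_edges_rewire = dps$p_edges,
      seconds = timing(ts))
  }

  # --- co-expression frequency ----------------------------------------
  coexpr <- NULL
  if (config$run_coexpr) {
    ts <- Sys.time()
    query <- config$query_gene %||%
      (if (!is.null(study$truth)) study$truth$module_specs[[1]]$gene_ids[1])
    if (!is.null(query) && length(modules_containing(modules, query))) {
      coexpr <- frequent_coexpressed(modules, mat, query,
                                     fraction = config$top_fraction,
                                     min_count = config$min_count)
      manifest$stages$coexpr <- list(
        query = query,
        n_modules_with_query = attr(coexpr, "n_modules"),
        n_frequent = sum(coexpr$frequent), seconds = timing(ts))
    }
  }

  manifest$combo_counts <- attr(modules, "combo_counts")
  manifest$total_seconds <- timing(t0)

  result <- list(matrix = mat, study = study, modules = modules,
                 overlap = ov, clusters = clusters, z = z,
                 phenotypes = phenotypes, activation = activation,
                 enrichment = enrichment, signature = signature,
                 network = network_stats, coexpr = coexpr,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Write every stage artefact in its plain-text exchange format; the
# manifest goes last so its presence marks a completed run.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_matrix_tsv(result$matrix, p("matrix.tsv"))
  write_modules_json(result$modules, p("modules.json"))
  sets <- lapply(result$modules$modules, function(m) names(m$genes))
  names(sets) <- paste0("M", seq_along(sets))
  write_gmt(sets, p("modules.gmt"))
  utils::write.table(unclass(result$overlap), p("overlap_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  cl_sets <- lapply(result$clusters, `[[`, "genes")
  names(cl_sets) <- vapply(result$clusters, `[[`, character(1), "cluster_id")
  write_gmt(cl_sets, p("module_clusters.gmt"))
  if (!is.null(result$activation))
    utils::write.table(unclass(result$activation), p("activation.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(result$enrichment))
    utils::write.table(result$enrichment, p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$signature)) {
    writeLines(result$signature$genes, p("signature_genes.txt"))
    utils::write.table(result$signature$model$importance,
                       p("signature_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$signature$performance$roc, p("roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$network)) {
    utils::write.table(result$network$centrality, p("subnetwork_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_edge_list(result$network$subnetwork, p("subnetwork_edges.tsv"))
  }
  if (!is.null(result$coexpr))
    utils::write.table(as.data.frame(result$coexpr),
                       p("frequent_coexpressed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}
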