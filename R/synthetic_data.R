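# Synthetic-data generators with planted ground truth. These emulate the
# pipeline's real substrate — a kidney toxicogenomics log-ratio matrix with
# overlapping co-expression structure, histopathology-scored condition
# metadata and a protein-interaction network — at desk scale, so every
# downstream stage can be validated against known truth.

#' Describe one planted bi-cluster
#'
#' A planted module is a gene set and a condition set whose cells receive an
#' additive shift on the log2 scale; per-gene signs allow anti-correlated
#' members, as real co-expression modules contain both up- and down-regulated
#' genes. Specs may overlap in genes and conditions.
#'
#' @param gene_ids character vector of member genes (non-empty).
#' @param condition_ids character vector of member conditions (non-empty).
#' @param effect_size mean log2-ratio shift, >= 0.
#' @param sign_pattern +1/-1 per gene; recycled if length 1.
#' @param condition_amplitudes optional non-negative per-condition
#'   activation strengths (mean ~1 keeps `effect_size` the mean shift);
#'   NULL means a constant shift, or sampling by [generate_matrix()] when
#'   its `amplitude_range` is set. Varying amplitudes are what make planted
#'   members actually co-expressed: a constant shift adds no correlated
#'   variation across the module's conditions.
#' @return an object of class `PlantedModuleSpec`.
#' @export
planted_module_spec <- function(gene_ids, condition_ids, effect_size,
                                sign_pattern = 1,
                                condition_amplitudes = NULL) {
  stopifnot(length(gene_ids) > 0, length(condition_ids) > 0,
            is.numeric(effect_size), effect_size >= 0)
  sign_pattern <- rep_len(sign_pattern, length(gene_ids))
  if (!all(sign_pattern %in% c(-1, 1)))
    stop("sign_pattern entries must be +1 or -1")
  if (!is.null(condition_amplitudes)) {
    condition_amplitudes <- rep_len(condition_amplitudes,
                                    length(condition_ids))
    stopifnot(all(condition_amplitudes >= 0))
  }
  structure(list(gene_ids = as.character(gene_ids),
                 condition_ids = as.character(condition_ids),
                 effect_size = effect_size,
                 sign_pattern = sign_pattern,
                 condition_amplitudes = condition_amplitudes),
            class = "PlantedModuleSpec")
}

#' Generate a log-ratio matrix with planted bi-clusters
#'
#' Background cells are drawn Normal(0, `noise_sd`); each planted spec adds
#' `sign_pattern[i] * effect_size * amplitude[j]` to its block, and
#' overlapping specs add their shifts. Effects are additive on the log2
#' scale, matching the log-ratio substrate.
#'
#' Under `amplitude_model = "constant"` every block cell gets the same
#' shift. That plants a mean effect but no co-expression: member genes show
#' no correlated variation across the module's conditions. The
#' `"exponential"` model gives each spec (without explicit amplitudes) the
#' deterministic Exp(1)-quantile profile, rescaled to mean exactly 1 — a
#' right-skewed activation pattern (most exposures engage the module
#' weakly, a few strongly, as dose–time potency distributions are) that
#' keeps `effect_size` the exact mean shift while making members genuinely
#' co-expressed.
#'
#' @param n_genes,n_conditions matrix dimensions (> 0).
#' @param specs list of [planted_module_spec()] objects; their IDs must be
#'   among the generated `g1..gN` / `c1..cM` identifiers.
#' @param noise_sd background standard deviation (> 0).
#' @param seed integer RNG seed; same seed gives bit-identical output.
#' @param amplitude_model "constant" (flat shift) or "exponential"
#'   (mean-1 Exp(1)-quantile activation profile) for specs without explicit
#'   `condition_amplitudes`.
#' @return list with `matrix` (genes x conditions) and `truth` (a
#'   `SyntheticTruth` carrying the specs — with realized amplitudes —
#'   noise level and seed).
#' @export
generate_matrix <- function(n_genes, n_conditions, specs = list(),
                            noise_sd = 1, seed = 1,
                            amplitude_model = c("constant", "exponential")) {
  if (n_genes < 1 || n_conditions < 1)
    stop("empty matrix rejected: n_genes and n_conditions must be >= 1")
  stopifnot(noise_sd > 0)
  amplitude_model <- match.arg(amplitude_model)
  gene_ids <- paste0("g", seq_len(n_genes))
  condition_ids <- paste0("c", seq_len(n_conditions))
  for (s in specs) {
    bad <- setdiff(s$gene_ids, gene_ids)
    if (length(bad)) stop("spec references unknown gene ID: ", bad[1])
    bad <- setdiff(s$condition_ids, condition_ids)
    if (length(bad)) stop("spec references unknown condition ID: ", bad[1])
  }
  specs <- lapply(specs, function(s) {
    if (is.null(s$condition_amplitudes)) {
      n <- length(s$condition_ids)
      amp <- if (amplitude_model == "constant") rep(1, n) else {
        q <- stats::qexp((seq_len(n) - 0.5) / n)
        # golden-ratio stride permutation spreads the quantiles over the
        # condition order, so any contiguous window of conditions sees the
        # full range of activation strengths (an ascending profile would
        # couple amplitude to condition index and starve nested specs)
        stride <- round(0.618 * n)
        while (stride > 1 && gcd2(stride, n) != 1) stride <- stride - 1
        if (stride < 1) stride <- 1
        ord <- ((seq_len(n) - 1) * stride) %% n + 1
        (q / mean(q))[ord]
      }
      s$condition_amplitudes <- amp
    }
    s
  })
  mat <- with_seed(seed,
    matrix(stats::rnorm(n_genes * n_conditions, sd = noise_sd),
           nrow = n_genes, dimnames = list(gene_ids, condition_ids)))
  for (s in specs) {
    mat[s$gene_ids, s$condition_ids] <-
      mat[s$gene_ids, s$condition_ids] +
      outer(s$sign_pattern * s$effect_size, s$condition_amplitudes)
  }
  truth <- structure(list(module_specs = specs, noise_sd = noise_sd,
                          seed = seed, phenotype_map = list(),
                          nephrotoxic_labels = character(0)),
                     class = "SyntheticTruth")
  list(matrix = mat, truth = truth)
}

#' Generate condition metadata with histopathology scores and class labels
#'
#' Conditions assigned to a phenotype receive integer histopathology scores
#' in 2..4 for that phenotype in every replicate (injury semantics: >= 2 in
#' all replicates); unassigned conditions score 0..1. Each condition also
#' carries a chemical, dose and exposure duration so class-based phenotype
#' definitions (highest dose per chemical) can be exercised.
#'
#' @param condition_ids all condition identifiers.
#' @param phenotype_assignments named list: phenotype label -> condition IDs.
#' @param class_labels named list: chemical-class label -> condition IDs.
#' @param n_replicates replicates per condition for histopathology scoring.
#' @param chemicals optional character vector (per condition); defaults to
#'   one chemical per pair of conditions so dose selection is non-trivial.
#' @param seed integer RNG seed.
#' @return list with `conditions` (condition_id, chemical, dose, duration,
#'   class) and `histopath` (condition_id, replicate, phenotype, score) in
#'   long format.
#' @export
generate_metadata <- function(condition_ids, phenotype_assignments = list(),
                              class_labels = list(), n_replicates = 3,
                              chemicals = NULL, seed = 1) {
  condition_ids <- as.character(condition_ids)
  for (ph in names(phenotype_assignments)) {
    bad <- setdiff(phenotype_assignments[[ph]], condition_ids)
    if (length(bad)) stop("unknown condition in phenotype ", ph, ": ", bad[1])
  }
  for (cl in names(class_labels)) {
    bad <- setdiff(class_labels[[cl]], condition_ids)
    if (length(bad)) stop("unknown condition in class ", cl, ": ", bad[1])
  }
  n <- length(condition_ids)
  if (is.null(chemicals))
    chemicals <- paste0("chem", ceiling(seq_len(n) / 2))
  chemicals <- rep_len(as.character(chemicals), n)

  cls <- rep(NA_character_, n)
  names(cls) <- condition_ids
  for (cl in names(class_labels)) cls[class_labels[[cl]]] <- cl

  with_seed(seed, {
    conditions <- data.frame(
      condition_id = condition_ids,
      chemical = chemicals,
      dose = sample(c(10, 30, 100), n, replace = TRUE),
      duration_days = sample(c(3, 5, 29), n, replace = TRUE),
      class = unname(cls),
      stringsAsFactors = FALSE
    )
    phenos <- names(phenotype_assignments)
    if (length(phenos) == 0L) {
      histopath <- data.frame(condition_id = character(0),
                              replicate = integer(0),
                              phenotype = character(0), score = integer(0),
                              stringsAsFactors = FALSE)
    } else {
      grid <- expand.grid(condition_id = condition_ids,
                          replicate = seq_len(n_replicates),
                          phenotype = phenos,
                          stringsAsFactors = FALSE)
      injured <- mapply(function(cid, ph)
        cid %in% phenotype_assignments[[ph]],
        grid$condition_id, grid$phenotype)
      grid$score <- ifelse(injured,
                           sample(2:4, nrow(grid), replace = TRUE),
                           sample(0:1, nrow(grid), replace = TRUE))
      histopath <- grid
    }
    list(conditions = conditions, histopath = histopath)
  })
}

#' Generate a protein-interaction network with a planted dense subgraph
#'
#' Erdős–Rényi background plus a fully connected clique on the planted
#' nodes; the result is a simple undirected graph (no self-loops, no
#' parallel edges).
#'
#' @param n_nodes node count; nodes are labelled `g1..gN` to align with the
#'   matrix generator's gene identifiers.
#' @param background_edge_prob edge probability in (0, 1) (0 allowed for a
#'   background-free graph).
#' @param planted_clique_nodes character vector of node IDs to clique.
#' @param seed integer RNG seed.
#' @return an igraph undirected simple graph.
#' @export
generate_ppi <- function(n_nodes, background_edge_prob = 0.01,
                         planted_clique_nodes = character(0), seed = 1) {
  stopifnot(n_nodes >= 1, background_edge_prob >= 0,
            background_edge_prob < 1)
  node_ids <- paste0("g", seq_len(n_nodes))
  planted_clique_nodes <- as.character(planted_clique_nodes)
  bad <- setdiff(planted_clique_nodes, node_ids)
  if (length(bad))
    stop("planted clique node outside the node set: ", bad[1])
  g <- with_seed(seed,
    igraph::sample_gnp(n_nodes, background_edge_prob, directed = FALSE))
  igraph::V(g)$name <- node_ids
  if (length(planted_clique_nodes) >= 2) {
    pairs <- utils::combn(planted_clique_nodes, 2)
    g <- igraph::add_edges(g, as.vector(pairs))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Build the default desk-scale synthetic study
#'
#' One call that assembles every input the pipeline needs: a 600-gene x
#' 60-condition log-ratio matrix with planted overlapping modules, condition
#' metadata with two histopathology phenotypes and two chemical classes, an
#' interaction network whose planted dense subgraph sits on the genes of the
#' injury modules, nephrotoxicity training labels, and a target gene set for
#' enrichment.
#'
#' The first two planted modules are "injury" modules: they are active in the
#' phenotype conditions and define the nephrotoxic class signal. The
#' remaining modules are active in non-injury conditions.
#'
#' @param n_genes,n_conditions matrix dimensions.
#' @param effect_size planted log2 shift.
#' @param noise_sd background noise standard deviation.
#' @param seed master RNG seed.
#' @return list with `matrix`, `truth`, `metadata`, `network`, `labels`
#'   (named character vector, "positive"/"negative"), and `target_genes`
#'   (the union of injury-module genes, the stand-in for a curated
#'   injury-relevant gene set).
#' @export
synthetic_study <- function(n_genes = 600, n_conditions = 60,
                            effect_size = 2, noise_sd = 1, seed = 1) {
  stopifnot(n_genes >= 200, n_conditions >= 40)
  gene_ids <- paste0("g", seq_len(n_genes))
  condition_ids <- paste0("c", seq_len(n_conditions))
  # 4 planted modules of 30-50 genes x 8-12 conditions; modules 1-2 share
  # genes and conditions (module clusters arise from shared members) and
  # carry the injury signal; module 4 mixes up- and down-regulated members.
  specs <- list(
    planted_module_spec(gene_ids[1:40], condition_ids[1:10], effect_size),
    planted_module_spec(gene_ids[31:80], condition_ids[5:14], effect_size),
    planted_module_spec(gene_ids[101:150], condition_ids[21:30], effect_size),
    planted_module_spec(gene_ids[161:190], condition_ids[33:40], effect_size,
                        sign_pattern = rep(c(1, -1), each = 15))
  )
  gen <- generate_matrix(n_genes, n_conditions, specs, noise_sd,
                         seed = derive_seed(seed, "matrix"),
                         amplitude_model = "exponential")
  injury_conds <- unique(c(specs[[1]]$condition_ids, specs[[2]]$condition_ids))
  class_conds <- list(C1 = condition_ids[21:30], C2 = condition_ids[33:40])
  metadata <- generate_metadata(
    condition_ids,
    phenotype_assignments = list(P1 = specs[[1]]$condition_ids,
                                 P2 = specs[[2]]$condition_ids),
    class_labels = class_conds,
    seed = derive_seed(seed, "metadata")
  )
  labels <- stats::setNames(
    ifelse(condition_ids %in% injury_conds, "positive", "negative"),
    condition_ids)
  target_genes <- unique(c(specs[[1]]$gene_ids, specs[[2]]$gene_ids))
  network <- generate_ppi(n_genes, background_edge_prob = 0.005,
                          planted_clique_nodes = specs[[1]]$gene_ids[1:12],
                          seed = derive_seed(seed, "ppi"))
  truth <- gen$truth
  truth$phenotype_map <- list(P1 = specs[[1]]$condition_ids,
                              P2 = specs[[2]]$condition_ids)
  truth$nephrotoxic_labels <- labels
  list(matrix = gen$matrix, truth = truth, metadata = metadata,
       network = network, labels = labels, target_genes = target_genes)
}

#' Write a synthetic study's ground truth as JSON
#'
#' @param truth a `SyntheticTruth`.
#' @param path destination path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  payload <- list(
    noise_sd = truth$noise_sd, seed = truth$seed,
    phenotype_map = truth$phenotype_map,
    nephrotoxic_labels = as.list(truth$nephrotoxic_labels),
    module_specs = lapply(truth$module_specs, function(s)
      list(gene_ids = s$gene_ids, condition_ids = s$condition_ids,
           effect_size = s$effect_size, sign_pattern = s$sign_pattern))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
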