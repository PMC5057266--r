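# Iterative Signature Algorithm (ISA) bi-clustering: normalization, seeding,
# signed iteration under gene/condition thresholds, convergence to a fixed
# point, uniqueness/robustness filtering, the size/intra-correlation filter,
# and the multi-threshold sweep-and-merge.
#
# A module is a signed fixed point of the alternating update
#   c_j = mean_{i in G} sign(g_i) * E_C[i, j],  keep |c_j| > t_c * sd(c)
#   g_i = mean_{j in C} sign(c_j) * E_G[i, j],  keep |g_i| > t_g * sd(g)
# where E_G is the gene-standardized and E_C the condition-standardized
# log-ratio matrix. Higher thresholds give smaller, more coherent modules.

#' ISA threshold parameters
#'
#' @param gene_threshold t_g > 0: genes are kept when their score exceeds
#'   t_g standard deviations of the score distribution.
#' @param condition_threshold t_c > 0: likewise for conditions.
#' @param max_iterations iteration budget per seed.
#' @param convergence_tol the gene set is considered converged when its
#'   Jaccard similarity to the previous iteration is >= 1 - convergence_tol
#'   for two consecutive iterations; in (0, 1].
#' @return an object of class `ISAParams`.
#' @export
isa_params <- function(gene_threshold, condition_threshold,
                       max_iterations = 100, convergence_tol = 0.01) {
  stopifnot(gene_threshold > 0, condition_threshold > 0,
            max_iterations >= 1,
            convergence_tol > 0, convergence_tol <= 1)
  structure(list(gene_threshold = gene_threshold,
                 condition_threshold = condition_threshold,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol),
            class = "ISAParams")
}

#' Construct a gene module
#'
#' @param genes named numeric vector of signed gene scores.
#' @param conditions named numeric vector of signed condition scores.
#' @param params the [isa_params()] that produced the module.
#' @param seed_index provenance: index of the seed that led to this module.
#' @param n_iterations iterations to convergence.
#' @return an object of class `GeneModule`.
#' @export
gene_module <- function(genes, conditions, params, seed_index = NA_integer_,
                        n_iterations = NA_integer_) {
  stopifnot(length(genes) > 0, length(conditions) > 0,
            !is.null(names(genes)), !is.null(names(conditions)))
  structure(list(genes = genes, conditions = conditions, params = params,
                 seed_index = seed_index, n_iterations = n_iterations),
            class = "GeneModule")
}

#' @export
print.GeneModule <- function(x, ...) {
  cat(sprintf("GeneModule: %d genes x %d conditions (t_g=%.1f, t_c=%.1f)\n",
              length(x$genes), length(x$conditions),
              x$params$gene_threshold, x$params$condition_threshold))
  invisible(x)
}

#' Construct a module collection
#'
#' @param modules list of [gene_module()] objects.
#' @param source_matrix_digest checksum of the matrix they were mined from.
#' @return an object of class `ModuleCollection`.
#' @export
module_collection <- function(modules, source_matrix_digest = NA_character_) {
  structure(list(modules = modules,
                 source_matrix_digest = source_matrix_digest),
            class = "ModuleCollection")
}

#' @export
length.ModuleCollection <- function(x) length(x$modules)

#' @export
print.ModuleCollection <- function(x, ...) {
  cat(sprintf("ModuleCollection with %d modules\n", length(x$modules)))
  invisible(x)
}

#' Standardize a log-ratio matrix for ISA
#'
#' Produces the gene-standardized matrix `E_G` (every row mean 0, sd 1) and
#' the condition-standardized matrix `E_C` (every column mean 0, sd 1).
#' Zero-variance rows or columns are standardized to all-zeros with a
#' warning rather than aborting, so degenerate inputs do not kill a sweep.
#'
#' @param mat log-ratio matrix, >= 2 genes and >= 2 conditions.
#' @return list with elements `E_G` and `E_C` (both genes x conditions).
#' @export
normalize_for_isa <- function(mat) {
  assert_log_ratio_matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  std_rows <- function(x) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance row(s) standardized to all-zeros")
      sdv[zero] <- 1
    }
    out <- (x - mu) / sdv
    out[zero, ] <- 0
    out
  }
  E_G <- std_rows(mat)
  E_C <- t(std_rows(t(mat)))
  list(E_G = E_G, E_C = E_C)
}

#' Generate ISA seed gene sets
#'
#' Seeds are hierarchical clusters of the gene correlation structure
#' (average-linkage tree on 1 - Pearson correlation of gene profiles, cut
#' into `n_hclust_clusters` groups) plus `n_random_seeds` uniformly sampled
#' gene sets.
#'
#' @param mat log-ratio matrix.
#' @param n_random_seeds number of random gene-set seeds, >= 0.
#' @param random_seed_size_range integer range of random seed sizes.
#' @param n_hclust_clusters number of hierarchical clusters; default scales
#'   as one cluster per ~40 genes (min 2).
#' @param rng_seed integer RNG seed.
#' @return list of character vectors (gene IDs), hierarchical clusters first.
#' @export
make_seeds <- function(mat, n_random_seeds = 100,
                       random_seed_size_range = c(5, 50),
                       n_hclust_clusters = NULL, rng_seed = 1) {
  assert_log_ratio_matrix(mat)
  stopifnot(n_random_seeds >= 0)
  if (n_random_seeds > 0 && max(random_seed_size_range) > nrow(mat))
    stop("requested random seed size exceeds the gene count")
  n_hclust_clusters <- n_hclust_clusters %||% max(2L, round(nrow(mat) / 40))
  cc <- suppressWarnings(stats::cor(t(mat)))
  cc[!is.finite(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  memb <- stats::cutree(hc, k = min(n_hclust_clusters, nrow(mat)))
  hier <- split(rownames(mat), memb)
  names(hier) <- NULL
  rand <- list()
  if (n_random_seeds > 0) {
    rand <- with_seed(rng_seed, {
      sizes <- sample(seq(random_seed_size_range[1],
                          random_seed_size_range[2]),
                      n_random_seeds, replace = TRUE)
      lapply(sizes, function(s) sample(rownames(mat), s))
    })
  }
  c(hier, rand)
}

# One alternating-update step from a signed gene vector; returns the new
# signed condition and gene score vectors (members only) or NULL when a set
# empties out.
isa_step <- function(gene_signs, E_G, E_C, t_g, t_c) {
  idx <- match(names(gene_signs), rownames(E_C))
  cscore <- as.vector(crossprod(E_C[idx, , drop = FALSE], gene_signs)) /
    length(gene_signs)
  keep_c <- abs(cscore) > t_c * stats::sd(cscore)
  if (!any(keep_c)) return(NULL)
  conds <- stats::setNames(cscore[keep_c], colnames(E_C)[keep_c])
  gscore <- as.vector(E_G[, names(conds), drop = FALSE] %*% sign(conds)) /
    length(conds)
  keep_g <- abs(gscore) > t_g * stats::sd(gscore)
  if (!any(keep_g)) return(NULL)
  genes <- stats::setNames(gscore[keep_g], rownames(E_G)[keep_g])
  list(genes = genes, conditions = conds)
}

#' Run the ISA iteration from one seed
#'
#' Alternates condition and gene scoring under the sd-scaled thresholds until
#' the gene set stabilizes (Jaccard similarity to the previous iteration
#' >= 1 - convergence_tol for two consecutive iterations) and the signed
#' gene/condition sets are an exact fixed point; re-applying one step to the
#' returned module reproduces it.
#'
#' @param seed_genes character vector of seed gene IDs (non-empty).
#' @param E_G,E_C standardized matrices from [normalize_for_isa()].
#' @param params an [isa_params()] object.
#' @param seed_index provenance tag carried into the module.
#' @return a [gene_module()] on convergence, or `NULL` when a set empties
#'   out or the iteration budget is exhausted.
#' @export
isa_iterate <- function(seed_genes, E_G, E_C, params,
                        seed_index = NA_integer_) {
  stopifnot(inherits(params, "ISAParams"), length(seed_genes) > 0)
  seed_genes <- intersect(seed_genes, rownames(E_G))
  if (length(seed_genes) == 0L) return(NULL)
  t_g <- params$gene_threshold
  t_c <- params$condition_threshold
  signs <- stats::setNames(rep(1, length(seed_genes)), seed_genes)
  prev_ids <- character(0)
  streak <- 0L
  state <- NULL
  for (it in seq_len(params$max_iterations)) {
    state <- isa_step(signs, E_G, E_C, t_g, t_c)
    if (is.null(state)) return(NULL)
    ids <- names(state$genes)
    new_signs <- sign(state$genes)
    exact <- identical(sort(ids), sort(prev_ids)) &&
      all(new_signs[sort(ids)] == signs[sort(ids)])
    if (jaccard(ids, prev_ids) >= 1 - params$convergence_tol)
      streak <- streak + 1L else streak <- 0L
    if (exact && streak >= 2L) {
      return(gene_module(state$genes, state$conditions, params,
                         seed_index = seed_index, n_iterations = it))
    }
    prev_ids <- ids
    signs <- new_signs
  }
  NULL
}

# Stability statistic behind the robustness filter: geometric mean of the
# summed squared gene scores and summed squared condition scores. Growing
# with module strength in BOTH dimensions, it separates genuine bi-clusters
# from the sharp single-condition fixed points that noise data produces
# (whose per-member mean scores are indistinguishable from real modules).
robustness_score <- function(module) {
  sqrt(sum(module$genes^2) * sum(module$conditions^2))
}

# Gene-score vectors of all modules aligned on a common gene universe
# (absent genes scored 0); columns = modules.
module_score_matrix <- function(modules, universe = NULL) {
  universe <- universe %||% sort(unique(unlist(lapply(modules, function(m)
    names(m$genes)))))
  out <- matrix(0, length(universe), length(modules),
                dimnames = list(universe, NULL))
  for (j in seq_along(modules))
    out[names(modules[[j]]$genes), j] <- modules[[j]]$genes
  out
}

#' Remove redundant modules
#'
#' Among any pair whose gene-score vectors (aligned on a common gene
#' universe, absent genes scored 0) correlate at or above the threshold,
#' only the first-encountered module survives; module order is therefore
#' part of the contract and kept deterministic by the sweep.
#'
#' @param collection a [module_collection()] or plain list of modules.
#' @param score_correlation_threshold redundancy cutoff, default 0.9.
#' @param universe gene identifiers to align score vectors on; defaults to
#'   the union of module gene sets, but the full matrix gene list (as the
#'   sweep passes) is preferable — with near-complete overlap the union
#'   leaves almost no zero coordinates and the correlation degenerates.
#' @return a [module_collection()] without redundant modules.
#' @export
filter_unique <- function(collection, score_correlation_threshold = 0.9,
                          universe = NULL) {
  modules <- if (inherits(collection, "ModuleCollection"))
    collection$modules else collection
  digest <- if (inherits(collection, "ModuleCollection"))
    collection$source_matrix_digest else NA_character_
  if (length(modules) <= 1L) return(module_collection(modules, digest))
  sm <- module_score_matrix(modules, universe)
  cc <- suppressWarnings(stats::cor(sm))
  cc[!is.finite(cc)] <- 0
  keep <- logical(length(modules))
  for (j in seq_along(modules)) {
    keep[j] <- !any(keep & cc[, j] >= score_correlation_threshold)
  }
  module_collection(modules[keep], digest)
}

#' Filter modules by robustness against a shuffled-matrix null
#'
#' Each module's robustness score is the geometric mean of its summed
#' squared gene scores and summed squared condition scores. The null
#' distribution is built by shuffling the matrix (independently permuting
#' every row, then every column), re-running the ISA over the same seeds and
#' parameters, and scoring whatever modules emerge. A module is kept iff its
#' score exceeds the chosen quantile of the null scores.
#'
#' @param collection modules to filter.
#' @param mat the log-ratio matrix they were mined from.
#' @param seeds the seed list used for mining (the null search re-uses it).
#' @param params the [isa_params()] for the null search.
#' @param n_shuffles number of shuffled matrices; 0 disables the filter with
#'   a warning.
#' @param quantile_cut quantile of null scores to beat, default 1 (the max).
#' @param rng_seed integer RNG seed.
#' @return a filtered [module_collection()].
#' @export
filter_robust <- function(collection, mat, seeds, params, n_shuffles = 100,
                          quantile_cut = 1, rng_seed = 1) {
  modules <- if (inherits(collection, "ModuleCollection"))
    collection$modules else collection
  digest <- if (inherits(collection, "ModuleCollection"))
    collection$source_matrix_digest else NA_character_
  if (n_shuffles == 0) {
    warning("n_shuffles = 0: robustness filter disabled")
    return(module_collection(modules, digest))
  }
  if (length(modules) == 0L) return(module_collection(modules, digest))
  null_scores <- with_seed(rng_seed, {
    unlist(lapply(seq_len(n_shuffles), function(s) {
      shuf <- mat
      for (i in seq_len(nrow(shuf))) shuf[i, ] <- sample(shuf[i, ])
      for (j in seq_len(ncol(shuf))) shuf[, j] <- sample(shuf[, j])
      norm <- suppressWarnings(normalize_for_isa(shuf))
      found <- lapply(seeds, function(sg)
        isa_iterate(sg, norm$E_G, norm$E_C, params))
      vapply(Filter(Negate(is.null), found), robustness_score, numeric(1))
    }))
  })
  if (length(null_scores) == 0L)
    return(module_collection(modules, digest))
  cut <- stats::quantile(null_scores, quantile_cut, names = FALSE)
  keep <- vapply(modules, robustness_score, numeric(1)) > cut
  module_collection(modules[keep], digest)
}

#' Filter modules by size and intra-module correlation
#'
#' Drops modules with more than `max_genes` genes or whose mean pairwise
#' Pearson correlation of member-gene profiles, computed over the module's
#' own conditions after aligning each profile by the sign of its gene score,
#' falls below `min_intra_correlation`. Single-gene modules have
#' intra-correlation 1 by convention.
#'
#' @param collection modules to filter.
#' @param mat the log-ratio matrix.
#' @param max_genes maximum gene count, default 200.
#' @param min_intra_correlation coherence cutoff, default 0.4.
#' @return a filtered [module_collection()].
#' @export
filter_size_correlation <- function(collection, mat, max_genes = 200,
                                    min_intra_correlation = 0.4) {
  modules <- if (inherits(collection, "ModuleCollection"))
    collection$modules else collection
  digest <- if (inherits(collection, "ModuleCollection"))
    collection$source_matrix_digest else NA_character_
  keep <- vapply(modules, function(m) {
    if (length(m$genes) > max_genes) return(FALSE)
    intra_module_correlation(m, mat) >= min_intra_correlation
  }, logical(1))
  module_collection(modules[keep], digest)
}

#' Mean pairwise intra-module correlation
#'
#' @param module a [gene_module()].
#' @param mat the log-ratio matrix.
#' @return mean pairwise Pearson correlation of sign-adjusted member
#'   profiles over the module's conditions; 1 for single-gene modules.
#' @export
intra_module_correlation <- function(module, mat) {
  if (length(module$genes) < 2L) return(1)
  x <- mat[names(module$genes), names(module$conditions), drop = FALSE]
  x <- x * sign(module$genes)
  cc <- suppressWarnings(stats::cor(t(x)))
  vals <- cc[upper.tri(cc)]
  vals[!is.finite(vals)] <- 0
  mean(vals)
}

#' Mine modules across a grid of thresholds and merge
#'
#' Runs the full per-combination pipeline — normalize, iterate every seed,
#' redundancy filter, robustness filter, size/correlation filter — for each
#' (gene threshold, condition threshold) pair of the grid, concatenates the
#' per-combination collections in deterministic order and removes redundant
#' modules across the union. The default 2.0–4.0 grid in steps of 0.5 gives
#' 25 combinations.
#'
#' @param mat log-ratio matrix.
#' @param gene_thresholds,condition_thresholds numeric grids (non-empty).
#' @param seeds seed list from [make_seeds()]; built automatically when NULL.
#' @param n_random_seeds random seeds when `seeds` is NULL.
#' @param rng_seed master integer seed for seeding and shuffles.
#' @param robust_n_shuffles shuffled matrices per combination for the
#'   robustness null (0 disables).
#' @param robust_quantile null quantile a module must beat.
#' @param max_genes,min_intra_correlation size/coherence filter settings.
#' @param min_genes,min_conditions minimum module dimensions: a
#'   co-expression module needs at least 2 genes, and the coherence cutoff
#'   is only estimable over enough conditions (pairwise correlation over
#'   <= 2 conditions is vacuously ±1), so degenerate fixed points below
#'   these sizes are discarded right after convergence.
#' @param unique_threshold redundancy correlation cutoff.
#' @param max_iterations,convergence_tol iteration controls.
#' @return a [module_collection()]; attribute `combo_counts` holds the
#'   per-combination module counts through each filter stage.
#' @export
sweep_and_merge <- function(mat,
                            gene_thresholds = seq(2, 4, by = 0.5),
                            condition_thresholds = seq(2, 4, by = 0.5),
                            seeds = NULL, n_random_seeds = 100,
                            rng_seed = 1,
                            robust_n_shuffles = 2, robust_quantile = 1,
                            max_genes = 200, min_intra_correlation = 0.4,
                            min_genes = 2, min_conditions = 3,
                            unique_threshold = 0.9,
                            max_iterations = 100, convergence_tol = 0.01) {
  assert_log_ratio_matrix(mat)
  if (length(gene_thresholds) == 0L || length(condition_thresholds) == 0L)
    stop("threshold grid must be non-empty")
  if (is.null(seeds))
    seeds <- make_seeds(mat, n_random_seeds = n_random_seeds,
                        rng_seed = derive_seed(rng_seed, "seeds"))
  norm <- normalize_for_isa(mat)
  all_modules <- list()
  counts <- list()
  for (t_g in gene_thresholds) {
    for (t_c in condition_thresholds) {
      params <- isa_params(t_g, t_c, max_iterations = max_iterations,
                           convergence_tol = convergence_tol)
      found <- list()
      for (k in seq_along(seeds)) {
        m <- isa_iterate(seeds[[k]], norm$E_G, norm$E_C, params,
                         seed_index = k)
        if (!is.null(m) && length(m$genes) >= min_genes &&
            length(m$conditions) >= min_conditions)
          found[[length(found) + 1L]] <- m
      }
      n_conv <- length(found)
      col <- filter_unique(found, unique_threshold,
                           universe = rownames(mat))
      n_uniq <- length(col)
      if (robust_n_shuffles > 0) {
        col <- filter_robust(col, mat, seeds, params,
                             n_shuffles = robust_n_shuffles,
                             quantile_cut = robust_quantile,
                             rng_seed = derive_seed(
                               rng_seed, sprintf("robust_%g_%g", t_g, t_c)))
      }
      n_rob <- length(col)
      col <- filter_size_correlation(col, mat, max_genes,
                                     min_intra_correlation)
      counts[[length(counts) + 1L]] <- data.frame(
        gene_threshold = t_g, condition_threshold = t_c,
        converged = n_conv, unique = n_uniq, robust = n_rob,
        final = length(col))
      all_modules <- c(all_modules, col$modules)
    }
  }
  merged <- filter_unique(all_modules, unique_threshold,
                          universe = rownames(mat))
  merged$source_matrix_digest <- matrix_digest(mat)
  attr(merged, "combo_counts") <- do.call(rbind, counts)
  merged
}
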