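# Z-score standardization of the log-ratio matrix, phenotype definitions
# from histopathology or chemical class, module-cluster activation scoring
# and gene-set over-representation tests.

#' Z-score standardize a log-ratio matrix per gene
#'
#' Z[i, j] = (X[i, j] - mu_i) / sigma_i with mu_i and sigma_i taken across
#' all conditions. Zero-variance rows become all-zero and are flagged in the
#' `zero_variance` attribute so they dilute but never inflate activation.
#'
#' @param mat log-ratio matrix with >= 2 conditions.
#' @return standardized matrix with attributes `gene_means`, `gene_sds`
#'   (retained for audit) and `zero_variance` (logical per gene).
#' @export
zscore_matrix <- function(mat) {
  assert_log_ratio_matrix(mat)
  stopifnot(ncol(mat) >= 2)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  zero <- sdv == 0
  sdv_safe <- ifelse(zero, 1, sdv)
  z <- (mat - mu) / sdv_safe
  z[zero, ] <- 0
  attr(z, "gene_means") <- mu
  attr(z, "gene_sds") <- sdv
  attr(z, "zero_variance") <- zero
  z
}

#' Define a phenotype from histopathology scores
#'
#' A condition represents a phenotype iff every one of its replicates scored
#' at or above `min_score` for that phenotype.
#'
#' @param histopath long data.frame with columns `condition_id`,
#'   `replicate`, `phenotype`, `score` (as produced by
#'   [generate_metadata()]).
#' @param phenotype_label phenotype to extract.
#' @param min_score injury threshold, default 2.
#' @return a `PhenotypeDefinition`: `label`, `condition_ids`, `origin`.
#' @export
define_phenotype_from_histopath <- function(histopath, phenotype_label,
                                            min_score = 2) {
  if (!phenotype_label %in% histopath$phenotype)
    stop("phenotype not present in histopathology table: ", phenotype_label)
  sub <- histopath[histopath$phenotype == phenotype_label, , drop = FALSE]
  ok <- tapply(sub$score, sub$condition_id, function(s) all(s >= min_score))
  structure(list(label = phenotype_label,
                 condition_ids = sort(names(ok)[ok]),
                 origin = "histopathology"),
            class = "PhenotypeDefinition")
}

#' Define a phenotype from a chemical exposure class
#'
#' Picks one exposure per chemical within the class: the highest-dose
#' condition, with deterministic tie-breaking by longest duration and then
#' lexicographic condition ID.
#'
#' @param conditions condition metadata data.frame with columns
#'   `condition_id`, `chemical`, `dose`, `duration_days`, `class`.
#' @param class_label class to extract.
#' @return a `PhenotypeDefinition` with origin `"class"`.
#' @export
define_phenotype_from_class <- function(conditions, class_label) {
  sub <- conditions[!is.na(conditions$class) &
                      conditions$class == class_label, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("class not present in condition metadata: ", class_label)
  picked <- vapply(split(sub, sub$chemical), function(d) {
    d <- d[order(-d$dose, -d$duration_days, d$condition_id), , drop = FALSE]
    d$condition_id[1]
  }, character(1))
  structure(list(label = class_label,
                 condition_ids = sort(unname(picked)),
                 origin = "class"),
            class = "PhenotypeDefinition")
}

#' Activation score of a module cluster for a phenotype
#'
#' The mean absolute Z-score over the cluster's genes and the phenotype's
#' conditions:
#' A = (1 / (N_m * N_p)) * sum_{i in m} sum_{j in p} |Z[i, j]|.
#' On null (standard-normal) data A converges to sqrt(2/pi) ~ 0.798.
#'
#' @param cluster a `ModuleCluster` (or any list with a `genes` element).
#' @param phenotype a `PhenotypeDefinition` (or list with `condition_ids`).
#' @param z matrix from [zscore_matrix()].
#' @return non-negative scalar.
#' @export
activation_score <- function(cluster, phenotype, z) {
  genes <- intersect(cluster$genes, rownames(z))
  conds <- intersect(phenotype$condition_ids, colnames(z))
  if (length(genes) == 0L || length(conds) == 0L)
    stop("cluster genes or phenotype conditions absent from the Z matrix")
  mean(abs(z[genes, conds, drop = FALSE]))
}

#' Activation table over clusters and phenotypes
#'
#' @param clusters list of `ModuleCluster` objects.
#' @param phenotypes list of `PhenotypeDefinition` objects.
#' @param z matrix from [zscore_matrix()].
#' @return clusters x phenotypes matrix of activation scores, class
#'   `ActivationTable`.
#' @export
activation_table <- function(clusters, phenotypes, z) {
  out <- matrix(NA_real_, length(clusters), length(phenotypes),
                dimnames = list(
                  vapply(clusters, `[[`, character(1), "cluster_id"),
                  vapply(phenotypes, `[[`, character(1), "label")))
  for (i in seq_along(clusters))
    for (j in seq_along(phenotypes))
      out[i, j] <- activation_score(clusters[[i]], phenotypes[[j]], z)
  structure(out, class = c("ActivationTable", class(out)))
}

#' Flag clusters specifically activated in injury phenotypes
#'
#' The specificity screen behind selecting injury-relevant module clusters:
#' a cluster is flagged when its activation in every injury phenotype sits
#' above the given quantile of the whole table and its activation in every
#' non-injury class sits below it.
#'
#' @param table an [activation_table()] result.
#' @param injury_labels phenotype column names counting as injury.
#' @param quantile_cut activation quantile separating "on" from "off",
#'   default 0.75.
#' @return character vector of flagged cluster ids.
#' @export
select_specific_clusters <- function(table, injury_labels,
                                     quantile_cut = 0.75) {
  stopifnot(all(injury_labels %in% colnames(table)))
  other <- setdiff(colnames(table), injury_labels)
  cut <- stats::quantile(as.vector(table), quantile_cut, names = FALSE)
  hit <- apply(table[, injury_labels, drop = FALSE] > cut, 1, all) &
    apply(table[, other, drop = FALSE] <= cut, 1, all)
  rownames(table)[hit]
}

#' Gene-set over-representation in a cluster
#'
#' One-sided Fisher/hypergeometric test of target-set enrichment among the
#' cluster's genes, against a gene universe.
#'
#' @param cluster_genes character vector of cluster member genes.
#' @param target_set character vector of target genes (e.g. curated
#'   injury-relevant genes).
#' @param universe character vector of all analysis genes; both inputs are
#'   intersected with it.
#' @param adjust optional p-value adjustment method for use by callers
#'   testing many clusters (see [enrich_clusters()]); unused here.
#' @return an `EnrichmentResult`: `k` (overlap), `n` (cluster size),
#'   `K` (target size in universe), `N` (universe size), `p_value`
#'   (one-sided over-representation), `overlap_genes`.
#' @export
enrich_gene_set <- function(cluster_genes, target_set, universe,
                            adjust = NULL) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  cluster_genes <- intersect(unique(cluster_genes), universe)
  target_set <- intersect(unique(target_set), universe)
  k <- length(intersect(cluster_genes, target_set))
  n <- length(cluster_genes)
  K <- length(target_set)
  N <- length(universe)
  # one-sided over-representation: P(X >= k), X ~ Hypergeometric(N, K, n)
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, n = n, K = K, N = N, p_value = p,
                 overlap_genes = sort(intersect(cluster_genes, target_set))),
            class = "EnrichmentResult")
}

#' Enrichment of a target set across all module clusters
#'
#' @param clusters list of `ModuleCluster` objects.
#' @param target_set,universe as in [enrich_gene_set()].
#' @param adjust optional multiple-testing method (e.g. "BH") applied across
#'   clusters via [stats::p.adjust()]; default none (per-cluster values).
#' @return data.frame with one row per cluster: cluster_id, k, n, K, N,
#'   p_value and (when `adjust` is given) p_adjusted.
#' @export
enrich_clusters <- function(clusters, target_set, universe, adjust = NULL) {
  rows <- lapply(clusters, function(cl) {
    e <- enrich_gene_set(cl$genes, target_set, universe)
    data.frame(cluster_id = cl$cluster_id, k = e$k, n = e$n, K = e$K,
               N = e$N, p_value = e$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(adjust)) out$p_adjusted <- stats::p.adjust(out$p_value, adjust)
  out
}
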