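# Frequent co-expression statistics: which genes keep appearing among the
# top correlates of a query gene (e.g. the kidney-injury biomarker Havcr1)
# across the modules that contain it, with gene-label-shuffle and
# leave-conditions-out controls and external fold-change concordance.

#' Modules containing a query gene
#'
#' @param collection a [module_collection()].
#' @param query gene identifier.
#' @return list of the member [gene_module()]s (possibly empty).
#' @export
modules_containing <- function(collection, query) {
  modules <- if (inherits(collection, "ModuleCollection"))
    collection$modules else collection
  Filter(function(m) query %in% names(m$genes), modules)
}

#' Top correlates of the query within one module
#'
#' Correlates every member gene's profile with the query's profile over the
#' module's own conditions (Pearson) and returns the top
#' ceil(fraction * (N_m - 1)) genes; the query is excluded from both the
#' candidate pool and the count. Ties at the cutoff are broken by gene ID;
#' zero-variance profiles get correlation -Inf and are never selected.
#'
#' @param module a [gene_module()] containing the query.
#' @param mat log-ratio matrix.
#' @param query gene identifier, member of the module.
#' @param fraction fraction of member genes to return, default 0.20.
#' @param all_conditions if TRUE correlate over every matrix condition
#'   instead of the module's own (default FALSE).
#' @return character vector of selected genes, correlation-ranked.
#' @export
top_correlated <- function(module, mat, query, fraction = 0.20,
                           all_conditions = FALSE) {
  members <- names(module$genes)
  if (!query %in% members) stop("query gene is not a module member: ", query)
  conds <- if (all_conditions) colnames(mat) else names(module$conditions)
  if (length(conds) < 2L) stop("module must span >= 2 conditions")
  candidates <- setdiff(members, query)
  if (length(candidates) == 0L) return(character(0))
  qp <- mat[query, conds]
  prof <- mat[candidates, conds, drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(t(prof), qp)))
  r[!is.finite(r)] <- -Inf
  names(r) <- candidates
  n_top <- ceiling(fraction * length(candidates))
  ord <- order(-r, names(r))
  names(r)[ord][seq_len(min(n_top, length(candidates)))]
}

#' Count gene occurrences across per-module top-correlate lists
#'
#' Genes occurring in at least `min_count` lists are the "frequently
#' co-expressed" set (the default 3 encodes "more than twice").
#'
#' @param top_lists list of character vectors from [top_correlated()].
#' @param min_count frequency threshold, default 3.
#' @return a `FrequencyTable` data.frame: gene, count, frequent; sorted by
#'   decreasing count then gene ID. Attribute `n_modules` records the
#'   number of lists.
#' @export
count_frequent <- function(top_lists, min_count = 3) {
  if (length(top_lists) == 0L)
    stop("no top-correlate lists supplied")
  tab <- table(unlist(top_lists))
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequent <- out$count >= min_count
  out <- out[order(-out$count, out$gene), ]
  rownames(out) <- NULL
  attr(out, "n_modules") <- length(top_lists)
  attr(out, "min_count") <- min_count
  class(out) <- c("FrequencyTable", class(out))
  out
}

#' Frequently co-expressed genes of a query, end to end
#'
#' Convenience wrapper: find the modules containing the query, take the top
#' correlates in each, and count frequencies.
#'
#' @param collection a [module_collection()].
#' @param mat log-ratio matrix.
#' @param query gene identifier.
#' @param fraction,min_count,all_conditions passed through.
#' @return a `FrequencyTable` (zero rows when the query is in no module or
#'   alone in all of them).
#' @export
frequent_coexpressed <- function(collection, mat, query, fraction = 0.20,
                                 min_count = 3, all_conditions = FALSE) {
  mods <- modules_containing(collection, query)
  if (length(mods) == 0L) {
    out <- data.frame(gene = character(0), count = integer(0),
                      frequent = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_modules") <- 0L
    attr(out, "min_count") <- min_count
    class(out) <- c("FrequencyTable", class(out))
    return(out)
  }
  lists <- lapply(mods, top_correlated, mat = mat, query = query,
                  fraction = fraction, all_conditions = all_conditions)
  count_frequent(lists, min_count = min_count)
}

#' Gene-label shuffle null for the frequent set
#'
#' Permutes the gene row labels of the matrix (a bijection: the multiset of
#' rows is unchanged), re-runs the entire module-mining pipeline and
#' recomputes the query's frequent set — the negative control: planted
#' structure should not survive label shuffling.
#'
#' @param mat log-ratio matrix.
#' @param query gene identifier.
#' @param sweep_args list of arguments for [sweep_and_merge()] (rng_seed is
#'   set from `rng_seed`).
#' @param fraction,min_count as in [frequent_coexpressed()].
#' @param rng_seed integer RNG seed (drives both the shuffle and the sweep).
#' @return a `FrequencyTable` from the shuffled data.
#' @export
shuffle_null <- function(mat, query, sweep_args = list(), fraction = 0.20,
                         min_count = 3, rng_seed = 1) {
  perm <- with_seed(derive_seed(rng_seed, "label_shuffle"),
                    sample(nrow(mat)))
  shuf <- mat
  rownames(shuf) <- rownames(mat)[perm]
  col <- do.call(sweep_and_merge,
                 c(list(mat = shuf,
                        rng_seed = derive_seed(rng_seed, "null_sweep")),
                   sweep_args))
  frequent_coexpressed(col, shuf, query, fraction = fraction,
                       min_count = min_count)
}

#' Leave-conditions-out robustness of the frequent set
#'
#' Drops a random fraction of conditions, re-runs the pipeline, and reports
#' how the query's frequent set changed.
#'
#' @param mat log-ratio matrix.
#' @param query gene identifier.
#' @param reference_frequent character vector: the frequent set on the full
#'   matrix (computed if NULL, using `sweep_args`).
#' @param drop_fraction fraction of conditions to drop (e.g. 0.05 or 0.10).
#' @param sweep_args list of arguments for [sweep_and_merge()].
#' @param fraction,min_count as in [frequent_coexpressed()].
#' @param rng_seed integer RNG seed.
#' @return list: `dropped_conditions`, `frequent` (new set), `retained`,
#'   `lost`, `gained`, `jaccard` (similarity to the reference set).
#' @export
leave_out_robustness <- function(mat, query, reference_frequent = NULL,
                                 drop_fraction = 0.05, sweep_args = list(),
                                 fraction = 0.20, min_count = 3,
                                 rng_seed = 1) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  n_drop <- round(drop_fraction * ncol(mat))
  if (ncol(mat) - n_drop < 3) stop("dropping that many conditions leaves < 3")
  if (is.null(reference_frequent)) {
    col0 <- do.call(sweep_and_merge,
                    c(list(mat = mat,
                           rng_seed = derive_seed(rng_seed, "ref_sweep")),
                      sweep_args))
    ft0 <- frequent_coexpressed(col0, mat, query, fraction, min_count)
    reference_frequent <- ft0$gene[ft0$frequent]
  }
  dropped <- if (n_drop > 0)
    with_seed(derive_seed(rng_seed, "leave_out"),
              sample(colnames(mat), n_drop)) else character(0)
  sub <- mat[, setdiff(colnames(mat), dropped), drop = FALSE]
  col <- do.call(sweep_and_merge,
                 c(list(mat = sub,
                        rng_seed = derive_seed(rng_seed, "lo_sweep")),
                   sweep_args))
  ft <- frequent_coexpressed(col, sub, query, fraction, min_count)
  new_set <- ft$gene[ft$frequent]
  list(dropped_conditions = sort(dropped),
       frequent = new_set,
       retained = intersect(reference_frequent, new_set),
       lost = setdiff(reference_frequent, new_set),
       gained = setdiff(new_set, reference_frequent),
       jaccard = jaccard(reference_frequent, new_set))
}

#' Spearman concordance of two fold-change vectors
#'
#' Rank correlation (average-rank tie handling) over the genes present in
#' both named vectors, restricted to `gene_set` when given — the
#' external-dataset concordance check.
#'
#' @param foldchange_a,foldchange_b named numeric vectors of log2 ratios.
#' @param gene_set optional gene subset.
#' @return list with `rho` (NA with `degenerate = TRUE` when either vector
#'   is all-tied), `n` genes used, `degenerate` flag.
#' @export
external_concordance <- function(foldchange_a, foldchange_b,
                                 gene_set = NULL) {
  common <- intersect(names(foldchange_a), names(foldchange_b))
  if (!is.null(gene_set)) common <- intersect(common, gene_set)
  if (length(common) < 3L)
    stop("need >= 3 genes present in both fold-change vectors")
  a <- foldchange_a[common]
  b <- foldchange_b[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(rho = NA_real_, n = length(common), degenerate = TRUE))
  list(rho = stats::cor(a, b, method = "spearman"),
       n = length(common), degenerate = FALSE)
}
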