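# Pairwise module overlap scores (sum of gene and condition Dice
# coefficients, range 0-2) and condensation of modules into module clusters
# by hierarchical clustering of the overlap matrix.

#' Overlap score between two modules
#'
#' OS(A, B) = 2|G(A) ∩ G(B)| / (|G(A)| + |G(B)|)
#'          + 2|E(A) ∩ E(B)| / (|E(A)| + |E(B)|),
#' the sum of the Dice coefficients of the gene sets and the condition sets.
#' 0 means fully disjoint modules, 2 complete overlap.
#'
#' @param a,b [gene_module()] objects with non-empty gene and condition sets.
#' @return a number in \[0, 2\]; symmetric in its arguments.
#' @export
overlap_score <- function(a, b) {
  ga <- names(a$genes); gb <- names(b$genes)
  ea <- names(a$conditions); eb <- names(b$conditions)
  if (length(ga) == 0L || length(gb) == 0L ||
      length(ea) == 0L || length(eb) == 0L)
    stop("overlap_score requires non-empty gene and condition sets")
  2 * length(intersect(ga, gb)) / (length(ga) + length(gb)) +
    2 * length(intersect(ea, eb)) / (length(ea) + length(eb))
}

#' Pairwise overlap-score matrix of a module collection
#'
#' @param collection a [module_collection()] with >= 2 modules.
#' @return symmetric numeric matrix (diagonal 2) with module ids
#'   `M1..Mk` as dimnames, class `OverlapMatrix`.
#' @export
overlap_matrix <- function(collection) {
  modules <- if (inherits(collection, "ModuleCollection"))
    collection$modules else collection
  k <- length(modules)
  if (k < 2L) stop("overlap_matrix requires at least 2 modules")
  ids <- paste0("M", seq_len(k))
  out <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in i:k) {
      os <- overlap_score(modules[[i]], modules[[j]])
      out[i, j] <- os
      out[j, i] <- os
    }
  }
  structure(out, class = c("OverlapMatrix", class(out)))
}

#' Condense modules into module clusters
#'
#' Transforms the overlap matrix into the dissimilarity d = 1 - OS/2 (so
#' identical modules are at distance 0, disjoint ones at 1), builds an
#' agglomerative tree and cuts it at `cut_height`. Each cluster carries the
#' union of its member modules' gene and condition sets — the only
#' definition consistent with overlapping modules.
#'
#' @param overlap an [overlap_matrix()] result.
#' @param collection the matching [module_collection()].
#' @param cut_height tree cut height in \[0, 1\], default 0.5.
#' @param linkage agglomeration method for [stats::hclust()], default
#'   "complete".
#' @return list of `ModuleCluster` objects: `cluster_id`, `member_modules`
#'   (integer indices), `genes`, `conditions`.
#' @export
cluster_modules <- function(overlap, collection, cut_height = 0.5,
                            linkage = "complete") {
  modules <- if (inherits(collection, "ModuleCollection"))
    collection$modules else collection
  stopifnot(nrow(overlap) == length(modules))
  if (cut_height < 0 || cut_height > 1)
    stop("cut_height must lie in [0, 1]")
  d <- stats::as.dist(1 - unclass(overlap) / 2)
  hc <- stats::hclust(d, method = linkage)
  memb <- stats::cutree(hc, h = cut_height)
  lapply(sort(unique(memb)), function(k) {
    idx <- which(memb == k)
    structure(list(
      cluster_id = paste0("MC", k),
      member_modules = idx,
      genes = sort(unique(unlist(lapply(modules[idx], function(m)
        names(m$genes))))),
      conditions = sort(unique(unlist(lapply(modules[idx], function(m)
        names(m$conditions)))))
    ), class = "ModuleCluster")
  })
}

#' @export
print.ModuleCluster <- function(x, ...) {
  cat(sprintf("%s: %d modules, %d genes, %d conditions\n", x$cluster_id,
              length(x$member_modules), length(x$genes),
              length(x$conditions)))
  invisible(x)
}
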