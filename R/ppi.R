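# Protein-interaction sub-network analysis: map a gene set onto the
# network, extract the largest connected component, test its node and edge
# counts against two null models (random node draws; exact-degree-preserving
# edge rewiring), and compute degree/betweenness with hub and high-traffic
# calling.

#' Extract the disease sub-network of a gene set
#'
#' Induces the subgraph on the genes that map to the network and returns its
#' largest connected component (ties broken by edge count, then by the
#' lexicographically smallest node set).
#'
#' @param gene_set character vector of gene/protein identifiers.
#' @param network igraph undirected simple graph with named vertices.
#' @return igraph subgraph (the sub-network).
#' @export
extract_subnetwork <- function(gene_set, network) {
  stopifnot(length(gene_set) > 0)
  mapped <- intersect(unique(gene_set), igraph::V(network)$name)
  if (length(mapped) == 0L)
    stop("no gene in the set maps to the network")
  sub <- igraph::induced_subgraph(network, mapped)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    stats_of <- lapply(best, function(k) {
      vs <- igraph::V(sub)$name[comp$membership == k]
      g <- igraph::induced_subgraph(sub, vs)
      list(edges = igraph::ecount(g), key = paste(sort(vs), collapse = ","))
    })
    ec <- vapply(stats_of, `[[`, numeric(1), "edges")
    best <- best[ec == max(ec)]
    if (length(best) > 1L) {
      keys <- vapply(stats_of[ec == max(ec)], `[[`, character(1), "key")
      best <- best[order(keys)][1]
    }
  }
  keep <- igraph::V(sub)$name[comp$membership == best[1]]
  igraph::induced_subgraph(sub, keep)
}

# Largest-component (nodes, edges) of the induced subgraph on `genes`.
component_size <- function(network, genes) {
  mapped <- intersect(genes, igraph::V(network)$name)
  if (length(mapped) == 0L) return(c(nodes = 0, edges = 0))
  sub <- igraph::induced_subgraph(network, mapped)
  comp <- igraph::components(sub)
  k <- which.max(comp$csize)
  vs <- igraph::V(sub)$name[comp$membership == k]
  g <- igraph::induced_subgraph(sub, vs)
  c(nodes = igraph::vcount(g), edges = igraph::ecount(g))
}

empirical_p <- function(null_values, observed, n_iter, pseudo_count) {
  hits <- sum(null_values >= observed)
  if (pseudo_count) (hits + 1) / (n_iter + 1) else hits / n_iter
}

#' Random-node-draw null test of sub-network size
#'
#' Draws `n_genes` random proteins from the network `n_iter` times, extracts
#' the largest connected component each time, and compares its node and edge
#' counts with the observed sub-network. By default p-values carry a +1
#' pseudo-count on numerator and denominator so they are never exactly 0;
#' `pseudo_count = FALSE` gives the raw hits/n_iter estimator.
#'
#' @param network igraph undirected simple graph.
#' @param n_genes number of proteins to draw per iteration.
#' @param observed_nodes,observed_edges observed sub-network size.
#' @param n_iter iterations, default 1000.
#' @param rng_seed integer RNG seed.
#' @param pseudo_count logical, default TRUE.
#' @return list with `p_nodes`, `p_edges`, `null_nodes`, `null_edges`.
#' @export
random_node_test <- function(network, n_genes, observed_nodes,
                             observed_edges, n_iter = 1000, rng_seed = 1,
                             pseudo_count = TRUE) {
  nv <- igraph::vcount(network)
  if (n_genes > nv) stop("n_genes exceeds the network size")
  nulls <- with_seed(rng_seed, {
    vapply(seq_len(n_iter), function(i) {
      genes <- sample(igraph::V(network)$name, n_genes)
      component_size(network, genes)
    }, numeric(2))
  })
  list(p_nodes = empirical_p(nulls["nodes", ], observed_nodes, n_iter,
                             pseudo_count),
       p_edges = empirical_p(nulls["edges", ], observed_edges, n_iter,
                             pseudo_count),
       null_nodes = nulls["nodes", ], null_edges = nulls["edges", ])
}

#' Degree-preserving rewiring null test of sub-network size
#'
#' Rewires the network by double-edge swaps (Q * |E| swap attempts per
#' iteration), which preserves every node's degree exactly, maps the same
#' gene set onto the rewired network, extracts the largest component, and
#' compares node and edge counts with the observed values as in
#' [random_node_test()].
#'
#' @param network igraph undirected simple graph with >= 2 edges.
#' @param gene_set gene identifiers defining the observed sub-network.
#' @param n_iter iterations, default 1000.
#' @param swap_rounds Q, swap attempts per edge per iteration; default 10.
#' @param rng_seed integer RNG seed.
#' @param pseudo_count as in [random_node_test()].
#' @return list with `p_nodes`, `p_edges`, `observed_nodes`,
#'   `observed_edges`, `null_nodes`, `null_edges`.
#' @export
degree_preserving_test <- function(network, gene_set, n_iter = 1000,
                                   swap_rounds = 10, rng_seed = 1,
                                   pseudo_count = TRUE) {
  if (igraph::ecount(network) < 2)
    stop("degree-preserving rewiring requires >= 2 edges")
  observed <- component_size(network, gene_set)
  n_swaps <- swap_rounds * igraph::ecount(network)
  nulls <- with_seed(rng_seed, {
    vapply(seq_len(n_iter), function(i) {
      g <- igraph::rewire(network, igraph::keeping_degseq(niter = n_swaps))
      component_size(g, gene_set)
    }, numeric(2))
  })
  list(p_nodes = empirical_p(nulls["nodes", ], observed["nodes"], n_iter,
                             pseudo_count),
       p_edges = empirical_p(nulls["edges", ], observed["edges"], n_iter,
                             pseudo_count),
       observed_nodes = unname(observed["nodes"]),
       observed_edges = unname(observed["edges"]),
       null_nodes = nulls["nodes", ], null_edges = nulls["edges", ])
}

#' Degree and betweenness of a sub-network with hub/traffic calling
#'
#' Degree is the incident edge count; betweenness is shortest-path
#' betweenness normalized by (n-1)(n-2)/2 (endpoints excluded), so values
#' lie in \[0, 1\]. Hubs are nodes with degree above `hub_threshold`;
#' high-traffic nodes have normalized betweenness above `traffic_threshold`.
#'
#' @param subgraph igraph graph (non-empty).
#' @param hub_threshold degree cutoff, default 5 (hub means > 5 connections).
#' @param traffic_threshold betweenness cutoff, default 0.09.
#' @return data.frame: node, degree, betweenness, is_hub, is_traffic; with
#'   attributes `n_nodes` and `n_edges`.
#' @export
centrality_stats <- function(subgraph, hub_threshold = 5,
                             traffic_threshold = 0.09) {
  if (igraph::vcount(subgraph) == 0) stop("empty subgraph")
  deg <- igraph::degree(subgraph)
  btw <- if (igraph::vcount(subgraph) > 2)
    igraph::betweenness(subgraph, normalized = TRUE)
  else
    stats::setNames(rep(0, igraph::vcount(subgraph)),
                    igraph::V(subgraph)$name)
  out <- data.frame(node = igraph::V(subgraph)$name,
                    degree = as.integer(deg[igraph::V(subgraph)$name]),
                    betweenness = unname(btw[igraph::V(subgraph)$name]),
                    stringsAsFactors = FALSE)
  out$is_hub <- out$degree > hub_threshold
  out$is_traffic <- out$betweenness > traffic_threshold
  attr(out, "n_nodes") <- igraph::vcount(subgraph)
  attr(out, "n_edges") <- igraph::ecount(subgraph)
  out
}
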