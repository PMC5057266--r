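# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, brute-force computation kept free of the code paths
# it verifies.

# Hypergeometric upper tail P(X >= k) from first principles (choose()
# arithmetic), for a universe of N with K targets and a draw of n.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- seq(max(k, 0, n + K - N), min(n, K))
  if (length(i) == 0L || k > min(n, K)) return(if (k <= 0) 1 else 0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Overlap score recomputed by naive set arithmetic on raw id vectors.
oracle_overlap <- function(ga, ea, gb, eb) {
  2 * length(intersect(ga, gb)) / (length(ga) + length(gb)) +
    2 * length(intersect(ea, eb)) / (length(ea) + length(eb))
}

# AUC as pairwise concordance: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, y) {
  pos <- scores[y == "positive"]
  neg <- scores[y == "negative"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Spearman rank correlation by the rank formula with average-rank ties.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Normalized betweenness by exhaustive shortest-path enumeration: BFS from
# every source, then explicit backtracking over predecessor lists to count
# the paths through every intermediate node.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    # BFS distances and predecessor lists from s
    dist <- rep(Inf, n); dist[s] <- 0
    preds <- vector("list", n)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- union(preds[[w]], v)
      }
    }
    # enumerate every shortest s->t path explicitly via the predecessor DAG
    all_paths <- function(v) {
      if (v == s) return(list(s))
      unlist(lapply(preds[[v]], function(p)
        lapply(all_paths(p), function(pp) c(pp, v))), recursive = FALSE)
    }
    for (t in (s + 1):n) {
      if (is.infinite(dist[t])) next
      paths <- all_paths(t)
      through <- numeric(n)
      for (pp in paths) {
        mid <- setdiff(pp, c(s, t))
        through[mid] <- through[mid] + 1
      }
      btw <- btw + through / length(paths)
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else numeric(n)
}

# Small deterministic module factory for overlap/clustering tests.
toy_module <- function(genes, conds, t = 2) {
  gene_module(stats::setNames(rep(1, length(genes)), genes),
              stats::setNames(rep(1, length(conds)), conds),
              isa_params(t, t))
}

# The standard 4-planted-module recovery scenario (disjoint, all-positive,
# exponential activation profile) used by ISA recovery experiments.
recovery_scenario <- function(seed, effect = 2) {
  specs <- list(
    planted_module_spec(paste0("g", 1:40), paste0("c", 1:10), effect),
    planted_module_spec(paste0("g", 101:150), paste0("c", 21:30), effect),
    planted_module_spec(paste0("g", 201:230), paste0("c", 33:40), effect),
    planted_module_spec(paste0("g", 301:360), paste0("c", 45:56), effect))
  gen <- generate_matrix(600, 60, specs, noise_sd = 1, seed = seed,
                         amplitude_model = "exponential")
  list(matrix = gen$matrix, specs = specs, truth = gen$truth)
}

best_gene_jaccard <- function(collection, gene_ids) {
  if (length(collection) == 0L) return(0)
  max(vapply(collection$modules, function(m) {
    length(intersect(names(m$genes), gene_ids)) /
      length(union(names(m$genes), gene_ids))
  }, numeric(1)))
}

# Co-expression frequency scenario: the query g1 and partners g2..g10 form a
# co-regulation program spanning three condition blocks; each block also
# activates 40 block-specific genes. Mined module variants of the blocks all
# contain the query, and the partners are its strongest correlates in each.
coexpr_scenario <- function(seed, effect = 3) {
  partners <- paste0("g", 1:10)
  specs <- c(
    lapply(1:3, function(k) planted_module_spec(
      c(partners, paste0("g", k * 100 + 1:40)),
      paste0("c", (k - 1) * 10 + 1:10), effect)),
    list(planted_module_spec(partners, paste0("c", 1:30), effect)))
  gen <- generate_matrix(1500, 120, specs, noise_sd = 1, seed = seed,
                         amplitude_model = "exponential")
  list(matrix = gen$matrix, specs = specs,
       partners = setdiff(partners, "g1"))
}
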