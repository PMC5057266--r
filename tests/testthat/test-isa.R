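# The ISA core: normalization, seeding, iteration to a fixed point, and the
# uniqueness / robustness / size-coherence filters with the threshold sweep.

test_that("normalize_for_isa standardizes rows of E_G and columns of E_C", {
  set.seed(21)
  m <- matrix(stats::rnorm(2000), nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:20)))
  norm <- normalize_for_isa(m)
  expect_lt(max(abs(rowMeans(norm$E_G))), 1e-9)
  expect_lt(max(abs(apply(norm$E_G, 1, stats::sd) - 1)), 1e-9)
  expect_lt(max(abs(colMeans(norm$E_C))), 1e-9)
  expect_lt(max(abs(apply(norm$E_C, 2, stats::sd) - 1)), 1e-9)
  # a hand-checked row
  m2 <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  eg <- normalize_for_isa(m2)$E_G
  expect_equal(unname(eg["g1", ]), c(-1, 0, 1))
  # idempotence: renormalizing an already gene-standardized matrix
  again <- normalize_for_isa(norm$E_G)$E_G
  expect_lt(max(abs(again - norm$E_G)), 1e-12)
})

test_that("zero-variance rows standardize to all-zeros with a warning", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m) <- paste0("c", 1:3)
  expect_warning(norm <- normalize_for_isa(m), "zero-variance")
  expect_identical(unname(norm$E_G["g2", ]), c(0, 0, 0))
})

test_that("make_seeds returns hierarchical blocks plus reproducible random
           sets", {
  # two perfectly correlated gene blocks force a 2-way split
  set.seed(5)
  base1 <- stats::rnorm(30); base2 <- stats::rnorm(30)
  m <- rbind(t(replicate(20, base1 + stats::rnorm(30, sd = 0.01))),
             t(replicate(20, base2 + stats::rnorm(30, sd = 0.01))))
  dimnames(m) <- list(paste0("g", 1:40), paste0("c", 1:30))
  seeds <- make_seeds(m, n_random_seeds = 0, n_hclust_clusters = 2)
  expect_length(seeds, 2)
  expect_setequal(sort(unlist(lapply(seeds, length))), c(20, 20))
  expect_true(any(vapply(seeds, function(s)
    setequal(s, paste0("g", 1:20)), logical(1))))
  s1 <- make_seeds(m, n_random_seeds = 10, random_seed_size_range = c(3, 8),
                   rng_seed = 7)
  s2 <- make_seeds(m, n_random_seeds = 10, random_seed_size_range = c(3, 8),
                   rng_seed = 7)
  expect_identical(s1, s2)
  expect_error(make_seeds(m, random_seed_size_range = c(5, 100)),
               "exceeds the gene count")
})

test_that("isa_iterate recovers a planted block from a partial seed and
           returns a fixed point", {
  spec <- planted_module_spec(paste0("g", 1:50), paste0("c", 1:10), 2)
  gen <- generate_matrix(600, 60, list(spec), noise_sd = 1, seed = 13,
                         amplitude_model = "exponential")
  norm <- normalize_for_isa(gen$matrix)
  params <- isa_params(2, 2)
  m <- isa_iterate(paste0("g", 1:10), norm$E_G, norm$E_C, params)
  expect_s3_class(m, "GeneModule")
  expect_gte(jacc <- length(intersect(names(m$genes), spec$gene_ids)) /
               length(union(names(m$genes), spec$gene_ids)), 0.9)
  # fixed point: one extra alternating step reproduces both sets exactly
  stp <- toxmodmine:::isa_step(sign(m$genes), norm$E_G, norm$E_C,
                               params$gene_threshold,
                               params$condition_threshold)
  expect_setequal(names(stp$genes), names(m$genes))
  expect_setequal(names(stp$conditions), names(m$conditions))
  expect_identical(sign(stp$genes[names(m$genes)]), sign(m$genes))
})

test_that("pure-noise seeds at stringent thresholds almost never converge", {
  gen <- generate_matrix(400, 40, noise_sd = 1, seed = 17)
  norm <- normalize_for_isa(gen$matrix)
  params <- isa_params(4, 4)
  set.seed(3)
  outcomes <- vapply(1:100, function(i) {
    m <- isa_iterate(sample(rownames(gen$matrix), 15),
                     norm$E_G, norm$E_C, params)
    is.null(m) || length(m$conditions) < 3
  }, logical(1))
  expect_gte(mean(outcomes), 0.95)
})

test_that("filter_unique keeps the first of any redundant pair", {
  a <- toy_module(paste0("g", 1:20), paste0("c", 1:5))
  b <- toy_module(paste0("g", 30:45), paste0("c", 7:9))
  col <- filter_unique(list(a, a, b))
  expect_length(col$modules, 2)
  col2 <- filter_unique(list(a, b))
  expect_length(col2$modules, 2)
  # a copy with 1 of 20 genes changed still correlates >= 0.9 when scores
  # are aligned on the full gene universe: collapsed, first one wins
  a_perturbed <- toy_module(c(paste0("g", 1:19), "g99"), paste0("c", 1:5))
  uni <- paste0("g", 1:100)
  dedup <- filter_unique(list(a, a_perturbed), universe = uni)
  expect_length(dedup$modules, 1)
  expect_identical(dedup$modules[[1]], a)
})

test_that("filter_size_correlation enforces the 200-gene cap and the 0.4
           coherence cutoff", {
  set.seed(9)
  m <- matrix(stats::rnorm(300 * 12), nrow = 300,
              dimnames = list(paste0("g", 1:300), paste0("c", 1:12)))
  big <- toy_module(paste0("g", 1:201), paste0("c", 1:8))
  expect_length(filter_size_correlation(list(big), m,
                                        max_genes = 200)$modules, 0)
  # module of identical rows: intra-correlation exactly 1
  m_id <- m; m_id[2:10, ] <- rep(m_id[1, ], each = 9)
  coherent <- toy_module(paste0("g", 1:10), paste0("c", 1:12))
  expect_equal(intra_module_correlation(coherent, m_id), 1)
  expect_length(filter_size_correlation(list(coherent), m_id)$modules, 1)
  # independent noise rows: mean pairwise r ~ 0, removed at 0.4
  noisy <- toy_module(paste0("g", 50:79), paste0("c", 1:8))
  expect_lt(abs(intra_module_correlation(noisy, m)), 0.25)
  expect_length(filter_size_correlation(list(noisy), m)$modules, 0)
  # single-gene convention
  single <- toy_module("g5", paste0("c", 1:4))
  expect_equal(intra_module_correlation(single, m), 1)
})

test_that("filter_robust retains strong planted modules and kills noise
           modules", {
  spec <- planted_module_spec(paste0("g", 1:50), paste0("c", 1:10), 3)
  gen <- generate_matrix(400, 40, list(spec), noise_sd = 1, seed = 19,
                         amplitude_model = "exponential")
  norm <- normalize_for_isa(gen$matrix)
  params <- isa_params(2, 2)
  seeds <- make_seeds(gen$matrix, n_random_seeds = 50, rng_seed = 4)
  found <- Filter(Negate(is.null), lapply(seeds, function(s)
    isa_iterate(s, norm$E_G, norm$E_C, params)))
  col <- filter_robust(filter_unique(found), gen$matrix, seeds, params,
                       n_shuffles = 1, rng_seed = 6)
  expect_gte(best_gene_jaccard(col, spec$gene_ids), 0.9)
  expect_warning(
    all_kept <- filter_robust(filter_unique(found), gen$matrix, seeds,
                              params, n_shuffles = 0),
    "disabled")
  expect_length(all_kept$modules, length(filter_unique(found)$modules))
  # deterministic given the seed
  col2 <- filter_robust(filter_unique(found), gen$matrix, seeds, params,
                        n_shuffles = 1, rng_seed = 6)
  expect_identical(length(col), length(col2))
})

test_that("sweep_and_merge executes the full grid and recovers planted
           structure", {
  sc <- recovery_scenario(seed = 1)
  col <- sweep_and_merge(sc$matrix, n_random_seeds = 100, rng_seed = 1)
  counts <- attr(col, "combo_counts")
  expect_identical(nrow(counts), 25L)
  expect_true(all(counts$unique <= counts$converged))
  expect_true(all(counts$robust <= counts$unique))
  expect_true(all(counts$final <= counts$robust))
  for (s in sc$specs)
    expect_gte(best_gene_jaccard(col, s$gene_ids), 0.8)
  # every emitted module is a fixed point of one more iteration
  norm <- normalize_for_isa(sc$matrix)
  for (m in col$modules[seq_len(min(5, length(col)))]) {
    stp <- toxmodmine:::isa_step(sign(m$genes), norm$E_G, norm$E_C,
                                 m$params$gene_threshold,
                                 m$params$condition_threshold)
    expect_setequal(names(stp$genes), names(m$genes))
  }
  expect_error(sweep_and_merge(sc$matrix, gene_thresholds = numeric(0)),
               "non-empty")
})

test_that("a single-combination grid is contained in itself after merge", {
  sc <- recovery_scenario(seed = 2)
  col <- sweep_and_merge(sc$matrix, gene_thresholds = 2,
                         condition_thresholds = 2,
                         n_random_seeds = 30, rng_seed = 2)
  expect_identical(nrow(attr(col, "combo_counts")), 1L)
  expect_gte(length(col), 1)
})

test_that("raising the gene threshold does not increase median module size", {
  sc <- recovery_scenario(seed = 3)
  norm <- normalize_for_isa(sc$matrix)
  seeds <- make_seeds(sc$matrix, n_random_seeds = 40, rng_seed = 3)
  median_size <- function(t_g) {
    found <- Filter(Negate(is.null), lapply(seeds, function(s)
      isa_iterate(s, norm$E_G, norm$E_C, isa_params(t_g, 2))))
    stats::median(vapply(found, function(m) length(m$genes), numeric(1)))
  }
  sizes <- vapply(c(2, 3, 4), median_size, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
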