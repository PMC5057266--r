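test_that("generate_matrix rejects degenerate and inconsistent inputs", {
  expect_error(generate_matrix(0, 10), "empty matrix")
  expect_error(generate_matrix(10, 0), "empty matrix")
  expect_error(
    generate_matrix(10, 5, list(planted_module_spec("g99", "c1", 1))),
    "unknown gene ID: g99")
  expect_error(
    generate_matrix(10, 5, list(planted_module_spec("g1", "c99", 1))),
    "unknown condition ID: c99")
  expect_error(planted_module_spec(character(0), "c1", 1))
  expect_error(planted_module_spec("g1", "c1", -1))
  expect_error(planted_module_spec("g1", "c1", 1, sign_pattern = 2))
})

test_that("background cells follow Normal(0, noise_sd) within 3 SE", {
  gen <- generate_matrix(500, 50, noise_sd = 1, seed = 42)
  m <- gen$matrix
  expect_identical(dim(m), c(500L, 50L))
  n <- length(m)
  expect_lt(abs(mean(m)), 3 / sqrt(n))            # SE of the mean = sd/sqrt(n)
  expect_lt(abs(stats::sd(m) - 1), 3 / sqrt(2 * n)) # SE of sd ~ sd/sqrt(2n)
})

test_that("planted blocks carry their effect and leave the background flat", {
  spec <- planted_module_spec(paste0("g", 1:50), paste0("c", 1:10), 2)
  gen <- generate_matrix(500, 50, list(spec), noise_sd = 1, seed = 7)
  block <- gen$matrix[spec$gene_ids, spec$condition_ids]
  rest <- gen$matrix[-(1:50), -(1:10)]
  expect_lt(abs(mean(block) - 2), 3 / sqrt(length(block)))
  expect_lt(abs(mean(rest)), 3 / sqrt(length(rest)))
})

test_that("overlapping specs add their shifts and signs are respected", {
  s1 <- planted_module_spec(paste0("g", 1:20), paste0("c", 1:5), 1.5)
  s2 <- planted_module_spec(paste0("g", 11:30), paste0("c", 3:8), 1.5,
                            sign_pattern = -1)
  gen <- generate_matrix(200, 20, list(s1, s2), noise_sd = 1, seed = 3)
  both <- gen$matrix[paste0("g", 11:20), paste0("c", 3:5)]
  only_neg <- gen$matrix[paste0("g", 21:30), paste0("c", 6:8)]
  expect_lt(abs(mean(both) - 0), 3 / sqrt(length(both)))   # +1.5 - 1.5
  expect_lt(abs(mean(only_neg) + 1.5), 3 / sqrt(length(only_neg)))
})

test_that("the exponential amplitude profile keeps the mean shift and plants
           co-expression", {
  spec <- planted_module_spec(paste0("g", 1:60), paste0("c", 1:10), 2)
  gen <- generate_matrix(300, 40, list(spec), noise_sd = 1, seed = 11,
                         amplitude_model = "exponential")
  amps <- gen$truth$module_specs[[1]]$condition_amplitudes
  expect_equal(mean(amps), 1, tolerance = 1e-12)
  block <- gen$matrix[spec$gene_ids, spec$condition_ids]
  expect_lt(abs(mean(block) - 2), 3 / sqrt(length(block)))
  # member genes now correlate over the module's own conditions
  cc <- stats::cor(t(block))
  expect_gt(mean(cc[upper.tri(cc)]), 0.4)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- list(planted_module_spec(paste0("g", 1:10), paste0("c", 1:4), 2))
  a <- generate_matrix(100, 20, spec, seed = 5)
  b <- generate_matrix(100, 20, spec, seed = 5)
  expect_identical(a$matrix, b$matrix)
  expect_false(identical(a$matrix, generate_matrix(100, 20, spec,
                                                   seed = 6)$matrix))
  g1 <- generate_ppi(50, 0.1, paste0("g", 1:5), seed = 2)
  g2 <- generate_ppi(50, 0.1, paste0("g", 1:5), seed = 2)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("metadata gives injured conditions >= 2 in every replicate and
           recovers assignments round-trip", {
  conds <- paste0("c", 1:8)
  md <- generate_metadata(conds,
                          phenotype_assignments = list(P1 = c("c1", "c2",
                                                              "c3")),
                          seed = 4)
  ph <- define_phenotype_from_histopath(md$histopath, "P1")
  expect_identical(ph$condition_ids, c("c1", "c2", "c3"))
  scores <- md$histopath[md$histopath$condition_id == "c4", "score"]
  expect_true(all(scores < 2))
  # a condition assigned to two phenotypes appears in both recovered sets
  md2 <- generate_metadata(conds,
                           phenotype_assignments = list(P1 = c("c1", "c2"),
                                                        P2 = c("c2", "c5")),
                           seed = 4)
  expect_true("c2" %in%
    define_phenotype_from_histopath(md2$histopath, "P1")$condition_ids)
  expect_true("c2" %in%
    define_phenotype_from_histopath(md2$histopath, "P2")$condition_ids)
  expect_error(generate_metadata(conds,
                                 phenotype_assignments = list(P1 = "c99")),
               "unknown condition")
  # no assignments -> empty histopathology table
  md0 <- generate_metadata(conds, seed = 1)
  expect_identical(nrow(md0$histopath), 0L)
})

test_that("generate_ppi plants exact cliques on an Erdos-Renyi background", {
  g <- generate_ppi(100, 0, planted_clique_nodes = paste0("g", 1:6),
                    seed = 1)
  clique <- igraph::induced_subgraph(g, paste0("g", 1:6))
  expect_equal(igraph::ecount(clique), choose(6, 2))
  expect_equal(igraph::ecount(g), choose(6, 2)) # p = 0: only the clique
  g0 <- generate_ppi(100, 0, seed = 1)
  expect_equal(igraph::ecount(g0), 0)
  # edge count within 3 SE of Binomial(C(200,2), 0.02)
  g2 <- generate_ppi(200, 0.02, seed = 9)
  n_pairs <- choose(200, 2)
  expect_lt(abs(igraph::ecount(g2) - n_pairs * 0.02),
            3 * sqrt(n_pairs * 0.02 * 0.98))
  expect_error(generate_ppi(5, 0.1, paste0("g", 1:9)), "outside the node set")
})

test_that("the network generator never emits self-loops or parallel edges", {
  for (s in 1:5) {
    g <- generate_ppi(80, 0.05, paste0("g", 1:10), seed = s)
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
  }
})

test_that("synthetic_study assembles consistent inputs for every stage", {
  st <- synthetic_study(seed = 2)
  expect_identical(dim(st$matrix), c(600L, 60L))
  expect_true(all(unlist(st$truth$phenotype_map) %in% colnames(st$matrix)))
  expect_setequal(names(st$labels), colnames(st$matrix))
  expect_true(all(st$target_genes %in% rownames(st$matrix)))
  expect_true(all(st$labels %in% c("positive", "negative")))
  # same seed, same study
  st2 <- synthetic_study(seed = 2)
  expect_identical(st$matrix, st2$matrix)
  expect_identical(st$metadata, st2$metadata)
})
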