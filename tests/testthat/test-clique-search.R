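test_that("patterns map to vertex subsets", {
  G <- planted_clique_graph(N = 4, k_planted = 2, seed = 14)$graph
  expect_equal(subgraph_from_pattern(G, c(0, 0, 0, 0)), integer(0))
  expect_equal(subgraph_from_pattern(G, c(1, 0, 1, 0)), c(1L, 3L))
  expect_equal(subgraph_from_pattern(G, c(3L, 1L)), c(1L, 3L))
  expect_error(subgraph_from_pattern(G, c(2L, 2L)), "collisions")
})

test_that("greedy shrinking removes low-degree, low-weight vertices first", {
  # a set that is already a clique is untouched
  K4 <- weighted_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(greedy_shrink(K4, 1:4, seed = 1), 1:4)
  # triangle {1,2,3} plus pendant 4 attached only to 1: pendant goes first
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[1, 3] <- A[2, 3] <- A[1, 4] <- 1
  A <- A + t(A)
  G <- weighted_graph(A)
  expect_equal(greedy_shrink(G, 1:4, seed = 1), 1:3)
  # equal-weight independent set: two seeded random removals leave a singleton
  I3 <- weighted_graph(matrix(0, 3, 3))
  out <- greedy_shrink(I3, 1:3, seed = 7)
  expect_length(out, 1L)
  expect_identical(out, greedy_shrink(I3, 1:3, seed = 7))
  # min-weight tie break: vertex 2 is lighter, so it is removed
  P2 <- weighted_graph(matrix(0, 2, 2), omega = c(2, 1))
  expect_equal(greedy_shrink(P2, 1:2, seed = 1), 1L)
})

test_that("local search grows cliques without ever losing weight", {
  A <- matrix(1, 3, 3) - diag(3)
  G <- weighted_graph(A)
  # an edge of the triangle completes within one iteration
  expect_equal(local_search(G, c(1L, 2L), iterations = 1, seed = 1), 1:3)
  # a maximal clique is a fixed point
  expect_equal(local_search(G, 1:3, iterations = 10, seed = 1), 1:3)
  expect_error(local_search(G, c(1L, 2L, 99L), iterations = 1, seed = 1))
  # monotone weight across iterations on random instances
  set.seed(47)
  for (rep in 1:10) {
    fx <- planted_clique_graph(N = 14, k_planted = 4, seed = 60 + rep)
    V <- sample(14, 6)
    C <- greedy_shrink(fx$graph, V, seed = rep)
    w_prev <- sum(fx$graph$omega[C])
    for (it in 1:5) {
      C <- local_search(fx$graph, C, iterations = 1, seed = rep + it)
      w <- sum(fx$graph$omega[C])
      expect_gte(w, w_prev - 1e-12)
      w_prev <- w
    }
    expect_true(gbsgraph:::is_clique(fx$graph, C))
    # fixed point is maximal
    final <- local_search(fx$graph, C, iterations = 50, seed = rep)
    expect_length(gbsgraph:::common_neighbors(fx$graph, final), 0L)
  }
})

test_that("shrink + search recovers a planted clique from partial seeds", {
  hits <- 0
  for (s in 1:30) {
    fx <- planted_clique_graph(N = 24, k_planted = 8, edge_p = 0.3,
                               weight_boost = 2, seed = 200 + s)
    start <- sample(fx$planted, 5)
    C <- greedy_shrink(fx$graph, start, seed = s)
    C <- local_search(fx$graph, C, iterations = 100, seed = s)
    if (setequal(C, fx$planted)) hits <- hits + 1
  }
  expect_equal(hits, 30L)
})

test_that("exact solver matches subset enumeration and igraph", {
  # K5 with unit weights
  K5 <- weighted_graph(matrix(1, 5, 5) - diag(5))
  mx <- max_weighted_clique_exact(K5)
  expect_equal(mx$vertices, 1:5)
  expect_equal(mx$weight, 5)
  # two disjoint triangles: the heavier one wins
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  G2 <- weighted_graph(A, omega = c(1, 1, 1, 2, 1, 1))
  mx <- max_weighted_clique_exact(G2)
  expect_equal(mx$vertices, 4:6)
  expect_equal(mx$weight, 4)
  # random graphs vs the brute-force subset oracle
  set.seed(48)
  for (rep in 1:15) {
    N <- sample(8:14, 1)
    fx <- planted_clique_graph(N = N, k_planted = 3, edge_p = 0.5,
                               weight_boost = 1.2, seed = 300 + rep)
    mx <- max_weighted_clique_exact(fx$graph)
    oracle <- oracle_max_clique_subsets(fx$graph$A, fx$graph$omega)
    expect_equal(mx$weight, oracle$weight, tolerance = 1e-10)
    expect_true(gbsgraph:::is_clique(fx$graph, mx$vertices))
  }
  # independent cross-check against igraph's cliquer (integer weights)
  if (requireNamespace("igraph", quietly = TRUE)) {
    for (rep in 1:5) {
      fx <- planted_clique_graph(N = 16, k_planted = 5, edge_p = 0.5,
                                 seed = 400 + rep)
      w_int <- pmax(1L, as.integer(round(fx$graph$omega * 1000)))
      Gi <- weighted_graph(fx$graph$A, w_int)
      g <- igraph::graph_from_adjacency_matrix(fx$graph$A,
                                               mode = "undirected")
      ig <- igraph::largest_weighted_cliques(g, vertex.weights = w_int)
      mx <- max_weighted_clique_exact(Gi)
      expect_equal(mx$weight, sum(w_int[as.integer(ig[[1]])]))
    }
  }
  expect_error(max_weighted_clique_exact(
    planted_clique_graph(N = 41, seed = 1)$graph), "resource guard")
})

test_that("postprocessing output is always a clique (fuzz)", {
  set.seed(49)
  for (rep in 1:25) {
    fx <- planted_clique_graph(N = 15, k_planted = 4,
                               edge_p = runif(1, 0.1, 0.8), seed = 500 + rep)
    V <- sample(15, sample(0:10, 1))
    C <- greedy_shrink(fx$graph, V, seed = rep)
    expect_true(gbsgraph:::is_clique(fx$graph, C))
    C2 <- local_search(fx$graph, C, iterations = 20, seed = rep)
    expect_true(gbsgraph:::is_clique(fx$graph, C2))
    expect_true(all(C2 %in% seq_len(15)))
  }
})

test_that("the clique pipeline tallies samples and scores success", {
  fx <- planted_clique_graph(N = 10, k_planted = 4, weight_boost = 3,
                             seed = 15)
  G <- fx$graph
  target <- max_weighted_clique_exact(G)
  # batch made of the max clique's own indicator patterns: success prob 1
  batch <- structure(list(patterns = replicate(20, target$vertices,
                                               simplify = FALSE),
                          N = 10, seed = 1, eta = 1, circuit_hash = "x"),
                     class = "sample_batch")
  stats <- run_clique_pipeline(G, batch, n_post = 5, seed = 2)
  expect_equal(stats$success_probability, 1)
  expect_equal(stats$n_samples, 20L)
  expect_equal(sum(stats$table$probability), 1)
  # replicate aggregation
  stats2 <- run_clique_pipeline(G, list(batch, batch), n_post = 5, seed = 2)
  expect_length(stats2$replicate_success, 2L)
  expect_error(run_clique_pipeline(G, list()), "sample_batch")
})

test_that("uniform baseline is uniform over subsets and reproducible", {
  G <- planted_clique_graph(N = 4, k_planted = 2, seed = 16)$graph
  b <- uniform_baseline(G, c(`4` = 1), n = 10, seed = 3)
  expect_true(all(vapply(b$patterns, identical, logical(1), 1:4)))
  expect_identical(uniform_baseline(G, c(`3` = 1), 50, seed = 4)$patterns,
                   uniform_baseline(G, c(`3` = 1), 50, seed = 4)$patterns)
  # multinomial uniformity over the 20 3-subsets of 6 vertices
  G6 <- planted_clique_graph(N = 6, k_planted = 2, seed = 17)$graph
  n <- 60000
  b <- uniform_baseline(G6, c(`3` = 1), n, seed = 5)
  keys <- vapply(b$patterns, paste, character(1), collapse = ",")
  counts <- table(keys)
  expect_equal(length(counts), 20L)
  p0 <- 1 / 20
  dev <- abs(as.numeric(counts) - n * p0) / sqrt(n * p0 * (1 - p0))
  expect_lt(max(dev), 4)
  expect_error(uniform_baseline(G6, c(`9` = 1), 5, seed = 1), "exceeds")
})
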