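# Network loading, LCC extraction, and the spin-glass partitioner against
# brute-force and planted-partition oracles.

test_that("edge lists are deduplicated and self-loops dropped", {
  e <- data.frame(from = c("a", "b", "a"), to = c("b", "a", "a"))
  expect_message(g <- load_network(e), "1 self-loops")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)
  expect_error(load_network(data.frame(from = character(0),
                                       to = character(0))), "empty")
})

test_that("two disjoint triangles form two components", {
  e <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
                  to = c("b", "c", "a", "y", "z", "x"))
  g <- suppressMessages(load_network(e))
  expect_equal(igraph::components(g)$no, 2)
})

test_that("SBM edge counts are near expectation", {
  cfg <- sim_config(n_subjects = 60, n_families = 30, n_snps = 100,
                    n_genes = 200, n_modules = 4, causal_module_ids = 1,
                    n_causal_genes = 2, sbm_p_in = 0.2, sbm_p_out = 0.01,
                    n_neighborhood = 10, n_qtl_phenotypes = 4, seed = 41)
  net <- simulate_network(cfg)
  n_in_pairs <- 4 * choose(50, 2)
  n_out_pairs <- choose(200, 2) - n_in_pairs
  expected <- 0.2 * n_in_pairs + 0.01 * n_out_pairs
  sd_e <- sqrt(0.2 * 0.8 * n_in_pairs + 0.01 * 0.99 * n_out_pairs)
  expect_lt(abs(igraph::ecount(net$network) - expected), 3 * sd_e)
})

test_that("largest connected component keeps the biggest piece, ties by name", {
  e <- data.frame(from = c("a", "b", "c", "d", "x", "y"),
                  to = c("b", "c", "d", "e", "y", "z"))
  g <- suppressMessages(load_network(e))
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c", "d", "e"))
  # connected graph is returned whole
  expect_equal(igraph::vcount(largest_connected_component(lcc)), 5)
  # equal sizes: the component with the smallest node name wins
  e2 <- data.frame(from = c("m", "n", "a", "b"), to = c("n", "o", "b", "c"))
  g2 <- suppressMessages(load_network(e2))
  expect_setequal(igraph::V(largest_connected_component(g2))$name,
                  c("a", "b", "c"))
})

test_that("the Hamiltonian matches a brute-force pair-sum evaluator", {
  set.seed(42)
  for (rep in 1:3) {
    g <- igraph::sample_gnp(12, 0.35)
    while (igraph::ecount(g) == 0) g <- igraph::sample_gnp(12, 0.35)
    igraph::V(g)$name <- sprintf("n%02d", 1:12)
    for (i in 1:60) {
      memb <- sample(1:4, 12, replace = TRUE)
      expect_equal(spinglass_hamiltonian(g, memb, gamma = 1),
                   brute_hamiltonian(g, memb, gamma = 1), tolerance = 1e-12)
      expect_equal(spinglass_hamiltonian(g, memb, gamma = 0.5),
                   brute_hamiltonian(g, memb, gamma = 0.5), tolerance = 1e-12)
    }
  }
})

test_that("two bridged cliques are split exactly at the enumeration optimum", {
  g <- two_cliques_graph(5)
  # enumerate all 2-colorings for the global minimum
  best_H <- Inf
  for (code in 0:(2^10 - 1)) {
    memb <- as.integer(intToBits(code))[1:10] + 1L
    H <- brute_hamiltonian(g, memb)
    if (H < best_H) best_H <- H
  }
  part <- spinglass_partition(g, q = 10, restarts = 3, seed = 43)
  expect_equal(part$H, best_H, tolerance = 1e-10)
  memb <- part$membership[igraph::V(g)$name]
  expect_length(unique(memb[1:5]), 1)
  expect_length(unique(memb[6:10]), 1)
  expect_false(memb[1] == memb[6])
  expect_equal(spinglass_hamiltonian(g, memb), part$H, tolerance = 1e-10)
})

test_that("a complete graph collapses to a single module", {
  g <- igraph::make_full_graph(8)
  igraph::V(g)$name <- letters[1:8]
  part <- spinglass_partition(g, q = 8, restarts = 2, seed = 44)
  expect_equal(length(part$sizes), 1)
})

test_that("disconnected input is refused", {
  e <- data.frame(from = c("a", "x"), to = c("b", "y"))
  g <- suppressMessages(load_network(e))
  expect_error(spinglass_partition(g, seed = 1), "disconnected")
})

test_that("partitions are seed-deterministic and seed-stable", {
  cfg <- sim_config(n_subjects = 60, n_families = 30, n_snps = 100,
                    n_genes = 200, n_modules = 4, causal_module_ids = 1,
                    n_causal_genes = 2, sbm_p_in = 0.2, sbm_p_out = 0.01,
                    n_neighborhood = 10, n_qtl_phenotypes = 4, seed = 45)
  lcc <- largest_connected_component(simulate_network(cfg)$network)
  p1 <- spinglass_partition(lcc, q = 25, restarts = 2, seed = 7)
  p2 <- spinglass_partition(lcc, q = 25, restarts = 2, seed = 7)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$H, p2$H)
  p3 <- spinglass_partition(lcc, q = 25, restarts = 2, seed = 8)
  expect_gte(adjusted_rand(p1$membership, p3$membership), 0.8)
})

test_that("minimizing H maximizes modularity against random partitions", {
  cfg <- sim_config(n_subjects = 60, n_families = 30, n_snps = 100,
                    n_genes = 150, n_modules = 3, causal_module_ids = 1,
                    n_causal_genes = 2, sbm_p_in = 0.2, sbm_p_out = 0.02,
                    n_neighborhood = 10, n_qtl_phenotypes = 4, seed = 46)
  lcc <- largest_connected_component(simulate_network(cfg)$network)
  part <- spinglass_partition(lcc, q = 25, restarts = 2, seed = 9)
  set.seed(10)
  for (i in 1:5) {
    rand_memb <- sample(1:4, igraph::vcount(lcc), replace = TRUE)
    expect_gt(part$modularity, igraph::modularity(lcc, rand_memb))
  }
  # H relates to Q at gamma = 1 up to a partition-independent constant:
  # -H = m*Q + sum(k^2)/(4m)
  m_edges <- igraph::ecount(lcc)
  const <- sum(igraph::degree(lcc)^2) / (4 * m_edges)
  expect_equal(part$modularity, (-part$H - const) / m_edges,
               tolerance = 1e-10)
})

test_that("partition summaries reduce to the right descriptive statistics", {
  expect_equal(partition_summary(c(2, 2, 2))$mean_size, 2)
  expect_equal(partition_summary(c(2, 2, 2))$sd_size, 0)
  expect_equal(partition_summary(c(10, 2351))$mean_size, 1180.5)
  s <- partition_summary(c(42))
  expect_equal(s$n_modules, 1)
  expect_equal(s$sd_size, 0)
})
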