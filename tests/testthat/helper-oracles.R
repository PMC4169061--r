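# Independent oracles used to check the package's implementations. These are
# deliberately written along different code paths than the functions they
# check (direct combinatorial sums, pair-by-pair loops, OLS algebra).

# upper-tail hypergeometric by direct combinatorial summation
enum_hypergeom_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# log-space variant for large N where choose() overflows
enum_hypergeom_upper_log <- function(N, K, n, k) {
  if (k == 0) return(1)
  ks <- k:min(n, K)
  lt <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  sum(exp(lt))
}

# exact HWE test by enumerating every admissible heterozygote count with
# factorial-ratio probabilities (conditional on the allele counts)
enum_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  hs <- seq(na %% 2, na, by = 2)
  logp <- vapply(hs, function(h) {
    paa <- (na - h) / 2
    pAA <- n - paa - h
    lfactorial(n) - lfactorial(pAA) - lfactorial(h) - lfactorial(paa) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- min(n_Aa, na)
  sum(pr[pr <= pr[match(obs, hs)] * (1 + 1e-7)])
}

# spin-glass Hamiltonian by explicit double loop over node pairs
brute_hamiltonian <- function(graph, membership, gamma = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  deg <- rowSums(A)
  two_m <- sum(deg)
  H <- 0
  n <- nrow(A)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (membership[i] == membership[j])
        H <- H - (A[i, j] - gamma * deg[i] * deg[j] / two_m)
    }
  }
  unname(H)
}

# two k-cliques joined by a single bridge edge
two_cliques_graph <- function(k = 5) {
  g1 <- igraph::make_full_graph(k)
  g2 <- igraph::make_full_graph(k)
  g <- igraph::disjoint_union(g1, g2)
  g <- igraph::add_edges(g, c(1, k + 1))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(2 * k))
  g
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small complete synthetic study used by several test files
small_study <- function(seed = 7) {
  simulate_study(sim_config(
    n_subjects = 120, n_families = 60, n_snps = 600, n_genes = 120,
    n_modules = 4, causal_module_ids = 2L, n_causal_genes = 6,
    sbm_p_in = 0.15, sbm_p_out = 0.01, n_proteins = 80,
    n_signal_proteins = 8, n_neighborhood = 30, n_qtl_phenotypes = 8,
    seed = seed))
}

small_params <- function(seed = 7) {
  pipeline_params(restarts = 3, spins = 25, stages = c(1e3, 1e4),
                  seed = seed)
}
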