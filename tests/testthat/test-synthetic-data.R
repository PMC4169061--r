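# Generator properties: configuration validation, LD and kinship structure,
# Hardy-Weinberg calibration, the planted latent factor, and determinism.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(n_subjects = 400, n_families = 100),
               "n_subjects <= 3")
  expect_error(sim_config(within_block_r = 1), "within_block_r < 1")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(sbm_p_in = 0.01, sbm_p_out = 0.05), "sbm_p_in")
  expect_error(sim_config(causal_module_ids = 99), "causal_module_ids")
  expect_error(sim_config(n_snps = 100, snps_per_gene = 5, n_genes = 10),
               "exceeds n_genes")
  expect_error(sim_config(n_snps = 100, n_genes = 100, n_modules = 10,
                          n_causal_genes = 12, causal_module_ids = 3),
               "not enough SNP-hosting genes")
})

test_that("uncorrelated blocks give near-zero between-SNP correlation", {
  cfg <- sim_config(n_subjects = 500, n_families = 250, n_snps = 200,
                    within_block_r = 0, n_causal_genes = 2,
                    causal_module_ids = 1, seed = 2)
  g <- simulate_genotypes(cfg)
  cc <- suppressWarnings(cor(g$genotypes$calls[, 1:30],
                             use = "pairwise.complete.obs"))
  off <- abs(cc[upper.tri(cc)])
  expect_lt(mean(off), 0.05)
  # sibling clusters shrink the effective sample size, so the null spread
  # of pairwise r is a little wider than 1/sqrt(500)
  expect_lt(quantile(off, 0.95), 0.12)
})

test_that("maf_range (0.5, 0.5) yields Hardy-Weinberg genotype proportions", {
  cfg <- sim_config(n_subjects = 500, n_families = 250, n_snps = 100,
                    within_block_r = 0, maf_range = c(0.5, 0.5),
                    n_causal_genes = 1, causal_module_ids = 1, seed = 3)
  g <- simulate_genotypes(cfg)
  tab <- table(g$genotypes$calls) / sum(!is.na(g$genotypes$calls))
  expect_equal(unname(tab["1"]), 0.5, tolerance = 0.03)
  expect_equal(unname(tab["0"] + tab["2"]), 0.5, tolerance = 0.03)
})

test_that("marginal allele frequencies track the configured range", {
  cfg <- sim_config(n_subjects = 400, n_families = 200, n_snps = 500,
                    within_block_r = 0.5, maf_range = c(0.2, 0.4),
                    n_causal_genes = 4, causal_module_ids = 1, seed = 5)
  g <- simulate_genotypes(cfg)
  f <- colMeans(g$genotypes$calls, na.rm = TRUE) / 2
  # mean of minor-orientation frequencies: E[min(f, 1-f)] with f ~ U(.2,.4)
  # is just below 0.3; allow 3 binomial SE around the configured mean
  se <- sqrt(0.3 * 0.7 / (2 * 400 * 500))
  expect_lt(abs(mean(f) - 0.3), 0.01 + 3 * se)
  expect_true(all(f <= 0.5 + 1e-12))
})

test_that("mean adjacent-SNP r-squared matches the frozen copula oracle", {
  # oracle: independent simulation of the thresholded equicorrelated copula
  # at r = 0.9 with frequencies U(0.1, 0.5) gives mean adjacent genotype
  # r^2 = 0.391 (MC SE 0.005); frozen band below
  cfg <- sim_config(n_subjects = 500, n_families = 250, n_snps = 1000,
                    ld_block_size = 10, within_block_r = 0.9,
                    n_causal_genes = 4, causal_module_ids = 1, seed = 1)
  g <- simulate_genotypes(cfg)
  r2 <- c()
  for (b in seq(1, 991, 10)) {
    cc <- suppressWarnings(cor(g$genotypes$calls[, b:(b + 9)],
                               use = "pairwise.complete.obs"))
    r2 <- c(r2, diag(cc[-1, -10])^2)
  }
  expect_gt(mean(r2, na.rm = TRUE), 0.36)
  expect_lt(mean(r2, na.rm = TRUE), 0.42)
})

test_that("siblings are more genotype-correlated than unrelated pairs", {
  cfg <- sim_config(n_subjects = 300, n_families = 150, n_snps = 500,
                    n_causal_genes = 4, causal_module_ids = 1, seed = 4)
  g <- simulate_genotypes(cfg)
  fam <- g$genotypes$family
  calls <- g$genotypes$calls
  multi <- names(table(fam))[table(fam) >= 2]
  sib <- vapply(multi, function(f) {
    i <- which(fam == f)[1:2]
    suppressWarnings(cor(calls[i[1], ], calls[i[2], ],
                         use = "pairwise.complete.obs"))
  }, numeric(1))
  set.seed(1)
  unrel <- vapply(1:80, function(k) {
    i <- sample(nrow(calls), 2)
    if (fam[i[1]] == fam[i[2]]) return(NA_real_)
    suppressWarnings(cor(calls[i[1], ], calls[i[2], ],
                         use = "pairwise.complete.obs"))
  }, numeric(1))
  expect_gt(mean(sib), mean(unrel, na.rm = TRUE))
})

test_that("latent factor drives metabolites with the closed-form PC1 share", {
  # equicorrelated one-factor model: loadings 1, noise SD 1 => top
  # eigenvalue share (k*lambda + sigma^2) / (k * (lambda + sigma^2)) = 9/16
  cfg <- sim_config(n_subjects = 500, n_families = 250, n_snps = 200,
                    n_causal_genes = 2, beta_snp = 0, causal_module_ids = 1,
                    metabolite_loadings = setNames(rep(1, 8), paste0("m", 1:8)),
                    noise_sd = 1, seed = 6)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, g$genotypes, g$snp_map)
  pc <- compute_met_pc(average_assessments(ph$metabolites), anchor = "m1")
  expect_equal(pc$variance_explained[1], 9 / 16, tolerance = 0.05)
})

test_that("noise-free single-factor metabolites recover the latent factor", {
  cfg <- sim_config(n_subjects = 200, n_families = 100, n_snps = 200,
                    n_causal_genes = 2, beta_snp = 0, causal_module_ids = 1,
                    metabolite_loadings = setNames(rep(1, 6), paste0("m", 1:6)),
                    noise_sd = 1e-6, assessment_sd_frac = 0, seed = 8)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, g$genotypes, g$snp_map)
  m <- average_assessments(ph$metabolites)
  expect_true(all(cor(m)[upper.tri(cor(m))] > 0.999))
  pc <- compute_met_pc(m, anchor = "m1")
  expect_gt(abs(cor(met_pc1(pc), ph$truth$latent[rownames(pc$scores)])), 0.99)
})

test_that("averaged assessments agree with the generator's pre-noise means", {
  cfg <- sim_config(n_subjects = 150, n_families = 75, n_snps = 200,
                    n_causal_genes = 2, causal_module_ids = 1, seed = 9)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, g$genotypes, g$snp_map)
  m <- average_assessments(ph$metabolites)
  truth <- ph$truth$metabolite_means
  diffs <- m[, colnames(truth)] - truth
  asd <- cfg$assessment_sd_frac * cfg$noise_sd
  expect_lt(sqrt(mean(diffs^2)), 1.2 * asd / sqrt(3))
})

test_that("a nonzero SNP effect with no resolvable causal SNPs is an error", {
  cfg <- sim_config(n_subjects = 60, n_families = 30, n_snps = 100,
                    n_causal_genes = 1, causal_module_ids = 1, seed = 1)
  g <- simulate_genotypes(cfg)
  bad_map <- g$snp_map
  bad_map$gene <- "nonexistent"
  expect_error(simulate_phenotypes(cfg, g$genotypes, bad_map),
               "no causal SNPs")
})

test_that("disconnected planted blocks survive network generation", {
  cfg <- sim_config(n_subjects = 60, n_families = 30, n_snps = 100,
                    n_genes = 40, n_modules = 2, causal_module_ids = 1,
                    n_causal_genes = 2, sbm_p_in = 0.5, sbm_p_out = 0,
                    n_neighborhood = 10, n_qtl_phenotypes = 4, seed = 2)
  net <- simulate_network(cfg)
  comp <- igraph::components(net$network)
  expect_gte(comp$no, 2)
  lcc <- largest_connected_component(net$network)
  modules_in_lcc <- unique(net$module_truth[igraph::V(lcc)$name])
  expect_length(modules_in_lcc, 1)
})

test_that("the generator is deterministic given the root seed", {
  cfg <- sim_config(n_subjects = 60, n_families = 30, n_snps = 120,
                    n_genes = 30, n_modules = 3, causal_module_ids = 2,
                    n_causal_genes = 3, n_proteins = 20,
                    n_signal_proteins = 3, n_neighborhood = 8,
                    n_qtl_phenotypes = 5, seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$genotypes$quality, s2$genotypes$quality)
  expect_identical(s1$metabolites, s2$metabolites)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(igraph::as_edgelist(s1$network),
                   igraph::as_edgelist(s2$network))
  expect_identical(s1$qtl_table, s2$qtl_table)
  expect_identical(s1$truth$latent, s2$truth$latent)
})
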