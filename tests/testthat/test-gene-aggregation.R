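# Gene models, the chi-square-sum statistic, and the LD-aware Monte-Carlo
# null, checked against closed forms and a phenotype-permutation oracle.

test_that("SNP-to-gene membership respects intervals and flanks", {
  snp_map <- data.frame(snp = c("a", "b"), chrom = "chr1",
                        pos = c(1000L, 1000L), stringsAsFactors = FALSE)
  calls <- matrix(sample(0:2, 40, TRUE), 20, 2,
                  dimnames = list(sprintf("s%02d", 1:20), c("a", "b")))
  g <- genotype_matrix(calls)
  ann <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    start = c(900L, 1050L), end = c(1100L, 1100L),
                    stringsAsFactors = FALSE)
  m0 <- build_gene_models(snp_map, ann, g, flank = 0)
  expect_setequal(m0$g1$snps, c("a", "b"))
  expect_null(m0$g2)
  expect_equal(attr(m0, "n_empty"), 1)
  m50k <- build_gene_models(snp_map, ann, g, flank = 50000)
  expect_setequal(m50k$g2$snps, c("a", "b"))
})

test_that("duplicated SNP columns give unit LD and duplicate genes error", {
  calls <- matrix(rep(sample(0:2, 20, TRUE), 2), 20, 2,
                  dimnames = list(sprintf("s%02d", 1:20), c("a", "b")))
  g <- genotype_matrix(calls)
  snp_map <- data.frame(snp = c("a", "b"), chrom = "chr1", pos = c(10L, 20L))
  ann <- data.frame(gene = "g1", chrom = "chr1", start = 1L, end = 100L)
  m <- build_gene_models(snp_map, ann, g, flank = 0)
  expect_equal(m$g1$R["a", "b"], 1.0, tolerance = 1e-12)
  ann2 <- rbind(ann, ann)
  expect_error(build_gene_models(snp_map, ann2, g), "duplicate gene ids")
})

test_that("the gene statistic is the chi-square quantile sum", {
  expect_equal(gene_statistic(0.05), qchisq(0.95, 1), tolerance = 1e-10)
  expect_equal(gene_statistic(0.05), 3.8415, tolerance = 1e-4)
  expect_equal(gene_statistic(c(1, 1)), 0)
  expect_equal(gene_statistic(rep(0.5, 7)), 7 * 0.4549364, tolerance = 1e-4)
  expect_warning(T0 <- gene_statistic(c(0, 0.5)), "clamped")
  expect_true(is.finite(T0))
})

test_that("a single-SNP gene reproduces the SNP p-value", {
  p_snp <- 0.03
  T <- gene_statistic(p_snp)
  res <- gene_pvalue(T, matrix(1, 1, 1), stages = 1e5, seed = 5)
  se <- sqrt(p_snp * (1 - p_snp) / 1e5)
  expect_lt(abs(res$p - p_snp), 3 * se)
})

test_that("identity LD matches the chi-square_k tail", {
  k <- 5
  T <- qchisq(0.98, k)
  res <- gene_pvalue(T, diag(k), stages = 1e4, seed = 6)
  truth <- 0.02
  expect_lt(abs(res$p - truth), 3 * sqrt(truth * (1 - truth) / 1e4))
})

test_that("perfect LD collapses to a single chi-square_1", {
  k <- 4
  R <- matrix(1, k, k)
  T <- 10
  truth <- pchisq(T / k, 1, lower.tail = FALSE)
  res <- gene_pvalue(T, R, stages = 1e4, seed = 7)
  expect_lt(abs(res$p - truth), 3 * sqrt(truth * (1 - truth) / 1e4))
})

test_that("gene p-values are reproducible, monotone in T, and floored", {
  R <- diag(3)
  r1 <- gene_pvalue(5, R, stages = c(1e3, 1e4), seed = 9)
  r2 <- gene_pvalue(5, R, stages = c(1e3, 1e4), seed = 9)
  expect_identical(r1, r2)
  ps <- vapply(c(1, 4, 9, 16), function(T)
    gene_pvalue(T, R, stages = 1e3, seed = 10)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
  big <- gene_pvalue(1e6, R, stages = c(1e3, 1e4), seed = 11)
  expect_equal(big$p, 1 / (big$n_sims + 1))
  expect_gt(big$n_sims, 1e3)  # small p escalated the schedule
})

test_that("non-PSD LD matrices are repaired, NaN ones rejected", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(R)$values), 0)
  res <- gene_pvalue(5, R, stages = 1e3, seed = 12)
  expect_true(res$p > 0 && res$p <= 1)
  R[1, 2] <- R[2, 1] <- NaN
  expect_error(gene_pvalue(5, R, stages = 1e3, seed = 12), "NA")
})

test_that("gene ranks agree with a phenotype-permutation oracle", {
  # 30 genes x 5 SNPs, modest LD; oracle = 2,000 phenotype permutations of
  # the covariate-residualized OLS scan, aggregated with the same statistic
  st <- simulate_study(sim_config(
    n_subjects = 100, n_families = 100, n_snps = 150, n_genes = 30,
    n_modules = 3, causal_module_ids = 1, n_causal_genes = 5,
    beta_snp = 0.6, n_proteins = 10, n_signal_proteins = 2,
    n_neighborhood = 6, n_qtl_phenotypes = 4, missing_call_rate = 0,
    low_quality_rate = 0, seed = 31))
  qc <- run_genotype_qc(st$genotypes)
  pc <- compute_met_pc(average_assessments(st$metabolites))
  y <- met_pc1(pc)
  scan <- run_genome_scan(y, qc$genotypes, st$covariates)
  models <- build_gene_models(st$snp_map, st$gene_annotation, qc$genotypes,
                              flank = 0)
  genes <- run_gene_test(scan, models, stages = c(1e3, 1e4), seed = 32)

  subj <- rownames(qc$genotypes$calls)
  cov <- st$covariates[match(subj, st$covariates$subject), ]
  X <- cbind(1, cov$age, cov$sex, cov$hei)
  Qx <- X %*% solve(crossprod(X))
  G <- qc$genotypes$calls[subj, , drop = FALSE]
  Gr <- G - Qx %*% crossprod(X, G)
  yv <- y[subj]
  pheno_p <- function(yy) {
    yr <- yy - Qx %*% crossprod(X, yy)
    bh <- crossprod(Gr, yr) / colSums(Gr^2)
    df <- length(yy) - 5
    rss <- sum(yr^2) - bh^2 * colSums(Gr^2)
    tt <- bh / sqrt(rss / df / colSums(Gr^2))
    2 * pt(-abs(tt), df)
  }
  obs_T <- vapply(names(models), function(g) {
    p <- setNames(pheno_p(yv)[match(models[[g]]$snps, colnames(G)), 1],
                  models[[g]]$snps)
    gene_statistic(p)
  }, numeric(1))
  set.seed(33)
  null_T <- matrix(NA_real_, 2000, length(models))
  for (b in 1:2000) {
    pp <- pheno_p(yv[sample(length(yv))])
    null_T[b, ] <- vapply(seq_along(models), function(gi) {
      idx <- match(models[[gi]]$snps, colnames(G))
      gene_statistic(pp[idx, 1])
    }, numeric(1))
  }
  perm_p <- vapply(seq_along(models), function(gi)
    (1 + sum(null_T[, gi] >= obs_T[gi])) / 2001, numeric(1))
  mc_p <- genes$p[match(names(models), genes$gene)]
  expect_gt(cor(rank(mc_p), rank(perm_p), method = "spearman"), 0.9)
})
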