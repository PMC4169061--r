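# Synthetic-cohort generator: sibling-clustered LD-block genotypes, a planted
# latent metabolite factor, a modular interaction network with planted
# enrichment, protein panels, and QTL intervals. Every downstream stage of the
# pipeline can be exercised on its output without any external data.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a small family-clustered cohort of children genotyped on a
#' dense array: 200 subjects in 100 sibling clusters of size 1-3, 5,000 SNPs in
#' 10-SNP LD blocks, 1,000 genes in a 10-block modular interaction network, a
#' planted latent metabolite factor loading on 8 metabolites, and a protein
#' panel of 1,000 aptamer-style analytes of which 50 carry signal.
#'
#' @param n_subjects number of genotyped subjects.
#' @param n_families number of sibling clusters (sizes 1-3; must satisfy
#'   `n_families <= n_subjects <= 3 * n_families`).
#' @param n_snps number of SNPs.
#' @param ld_block_size SNPs per LD block (last block may be shorter).
#' @param within_block_r latent haplotype correlation within a block, in \[0, 1).
#' @param maf_range range of simulated minor-allele frequencies, in (0, 0.5].
#' @param n_genes genes in the interaction network (genes hosting SNPs are the
#'   first `ceiling(n_snps / snps_per_gene)` of them).
#' @param snps_per_gene SNPs per SNP-hosting gene.
#' @param n_modules planted network blocks.
#' @param sbm_p_in,sbm_p_out stochastic-block-model edge probabilities
#'   (within/between block); `sbm_p_in > sbm_p_out` required.
#' @param n_causal_genes genes carrying phenotype signal.
#' @param causal_module_ids module indices hosting the causal genes.
#' @param beta_snp phenotype effect per minor allele at each causal SNP, in
#'   phenotype SD units before standardization.
#' @param gamma_age,gamma_sex covariate effects entering the latent factor.
#' @param metabolite_loadings named vector of metabolite loadings on the
#'   latent factor.
#' @param noise_sd metabolite-level noise SD.
#' @param assessment_sd_frac assessment-level noise SD as a fraction of
#'   `noise_sd` (three assessments per subject are generated).
#' @param n_proteins,n_signal_proteins protein panel size and number of
#'   proteins carrying signal.
#' @param protein_beta log2-scale protein effect of the latent factor.
#' @param n_neighborhood size of the micronutrient-neighborhood gene list.
#' @param neighborhood_frac fraction of neighborhood genes placed inside the
#'   first causal module.
#' @param n_qtl_phenotypes number of QTL phenotypes (one is planted over the
#'   causal genes).
#' @param qtl_overlap_frac fraction of causal genes covered by the planted
#'   phenotype's QTL windows.
#' @param missing_call_rate,low_quality_rate per-call rates of missingness and
#'   of low (< 0.7) call quality, in \[0, 1).
#' @param seed root seed; all stage sub-seeds derive from it via
#'   [substream_seed()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 200L,
                       n_families = 100L,
                       n_snps = 5000L,
                       ld_block_size = 10L,
                       within_block_r = 0.8,
                       maf_range = c(0.1, 0.5),
                       n_genes = 1000L,
                       snps_per_gene = 5L,
                       n_modules = 10L,
                       sbm_p_in = 0.08,
                       sbm_p_out = 0.004,
                       n_causal_genes = 12L,
                       causal_module_ids = 3L,
                       beta_snp = 0.5,
                       gamma_age = 0.1,
                       gamma_sex = 0.2,
                       metabolite_loadings = c(
                         vitamin_A = -0.8, vitamin_D = 0.2, vitamin_E = 0.9,
                         riboflavin = 0.1, thiamine = 0.8, pyridoxal = 0.8,
                         homocysteine = -0.7, SAM_SAH = -0.7),
                       noise_sd = 0.8,
                       assessment_sd_frac = 0.3,
                       n_proteins = 1000L,
                       n_signal_proteins = 50L,
                       protein_beta = 0.8,
                       n_neighborhood = 60L,
                       neighborhood_frac = 0.6,
                       n_qtl_phenotypes = 36L,
                       qtl_overlap_frac = 0.8,
                       missing_call_rate = 0.001,
                       low_quality_rate = 0.001,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_families = as.integer(n_families),
    n_snps = as.integer(n_snps), ld_block_size = as.integer(ld_block_size),
    within_block_r = within_block_r, maf_range = as.numeric(maf_range),
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    n_modules = as.integer(n_modules), sbm_p_in = sbm_p_in,
    sbm_p_out = sbm_p_out, n_causal_genes = as.integer(n_causal_genes),
    causal_module_ids = as.integer(causal_module_ids), beta_snp = beta_snp,
    gamma_age = gamma_age, gamma_sex = gamma_sex,
    metabolite_loadings = metabolite_loadings, noise_sd = noise_sd,
    assessment_sd_frac = assessment_sd_frac,
    n_proteins = as.integer(n_proteins),
    n_signal_proteins = as.integer(n_signal_proteins),
    protein_beta = protein_beta,
    n_neighborhood = as.integer(n_neighborhood),
    neighborhood_frac = neighborhood_frac,
    n_qtl_phenotypes = as.integer(n_qtl_phenotypes),
    qtl_overlap_frac = qtl_overlap_frac,
    missing_call_rate = missing_call_rate,
    low_quality_rate = low_quality_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_subjects > 0L, n_families > 0L, n_snps > 0L, ld_block_size > 0L,
      n_genes > 0L, snps_per_gene > 0L, n_modules > 0L,
      n_families <= n_subjects, n_subjects <= 3L * n_families,
      within_block_r >= 0, within_block_r < 1,
      length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
      maf_range[1] <= maf_range[2],
      sbm_p_in > sbm_p_out, sbm_p_in <= 1, sbm_p_out >= 0,
      n_causal_genes >= 0L,
      all(causal_module_ids >= 1L & causal_module_ids <= n_modules),
      length(metabolite_loadings) >= 2L, noise_sd > 0,
      n_signal_proteins <= n_proteins,
      missing_call_rate >= 0, missing_call_rate < 1,
      low_quality_rate >= 0, low_quality_rate < 1)
    # every SNP-hosting gene must exist; causal genes must host SNPs
    m <- ceiling(n_snps / snps_per_gene)
    if (m > n_genes) stop("n_snps / snps_per_gene exceeds n_genes")
    run <- ceiling(n_genes / n_modules)
    hosting_per_module <- tabulate(((seq_len(m) - 1L) %/% run) + 1L,
                                   n_modules)
    if (n_causal_genes > sum(hosting_per_module[causal_module_ids]))
      stop("not enough SNP-hosting genes in the causal modules")
  })
  invisible(cfg)
}

#' Deterministic genomic layout and module assignment of the synthetic genes
#'
#' Genes are placed end-to-end on one chromosome (20 kb gene bodies, 200 kb
#' spacing, so default 50 kb flanks never overlap a neighbouring gene) and
#' assigned to network modules in contiguous genomic runs, emulating the
#' genomic clustering of functionally related genes; in particular, LD
#' between neighbouring genes then stays mostly within one module. Purely
#' arithmetic: no randomness, so the genotype and network generators agree
#' on it without sharing state.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with gene, chrom, start, end (1-based inclusive), module.
#' @export
gene_layout <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  run <- ceiling(cfg$n_genes / cfg$n_modules)
  data.frame(
    gene = sprintf("g%04d", g),
    chrom = "chr1",
    start = (g - 1L) * 200000L + 1L,
    end = (g - 1L) * 200000L + 20000L,
    module = ((g - 1L) %/% run) + 1L,
    stringsAsFactors = FALSE)
}

# causal genes: seeded sample of SNP-hosting genes inside the causal modules
pick_causal_genes <- function(cfg) {
  if (cfg$n_causal_genes == 0L) return(character(0))
  lay <- gene_layout(cfg)
  hosting <- seq_len(ceiling(cfg$n_snps / cfg$snps_per_gene))
  pool <- lay$gene[hosting][lay$module[hosting] %in% cfg$causal_module_ids]
  set.seed(substream_seed(cfg$seed, 11L))
  sort(sample(pool, cfg$n_causal_genes))
}

#' Simulate family-clustered genotypes in LD blocks
#'
#' Haplotypes are drawn per LD block from an equicorrelated Gaussian copula
#' (pairwise latent correlation `within_block_r`) thresholded at each SNP's
#' simulated allele frequency. Each family has four parental haplotypes per
#' block; each child inherits one maternal and one paternal haplotype chosen
#' independently per block, so siblings share each parental haplotype with
#' probability 1/2 per block. The minor allele is oriented per SNP after
#' simulation (empirical frequency <= 0.5; at exactly 0.5 the alternate allele
#' stays minor). Per-call quality is Uniform(0.7, 1) except a
#' `low_quality_rate` fraction drawn Uniform(0, 0.7); a `missing_call_rate`
#' fraction of calls is set missing.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a `genotype_matrix`: integer call matrix
#'   subjects x SNPs with NA for missing, plus a parallel quality matrix and a
#'   family factor) and `snp_map` (SNP id, chrom, pos, alleles, gene).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, 1L))
  n <- cfg$n_subjects
  p <- cfg$n_snps

  freq <- runif(p, cfg$maf_range[1], cfg$maf_range[2])

  # family sizes in 1..3, adjusted to sum exactly to n_subjects
  sizes <- sample(1:3, cfg$n_families, replace = TRUE)
  while (sum(sizes) > n) {
    i <- which.max(sizes); sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < n) {
    i <- which.min(sizes)
    if (sizes[i] >= 3L) stop("cannot fit n_subjects into n_families")
    sizes[i] <- sizes[i] + 1L
  }
  sizes <- sizes[sizes > 0L]
  family <- factor(rep(sprintf("fam%03d", seq_along(sizes)), sizes))
  fam_idx <- rep(seq_along(sizes), sizes)

  blocks <- split(seq_len(p), ceiling(seq_len(p) / cfg$ld_block_size))
  n_hap <- 4L * length(sizes)
  r <- cfg$within_block_r
  calls <- matrix(0L, n, p)
  for (b in blocks) {
    k <- length(b)
    z <- sqrt(r) * rnorm(n_hap) +
      sqrt(1 - r) * matrix(rnorm(n_hap * k), n_hap, k)
    hap <- (z < matrix(qnorm(freq[b]), n_hap, k, byrow = TRUE)) + 0L
    mat_choice <- rbinom(n, 1L, 0.5)
    pat_choice <- rbinom(n, 1L, 0.5)
    mat <- (fam_idx - 1L) * 4L + 1L + mat_choice
    pat <- (fam_idx - 1L) * 4L + 3L + pat_choice
    calls[, b] <- hap[mat, , drop = FALSE] + hap[pat, , drop = FALSE]
  }

  # orient to minor allele; ties at 0.5 keep the alternate allele as minor
  fhat <- colMeans(calls) / 2
  flip <- fhat > 0.5
  calls[, flip] <- 2L - calls[, flip]
  alleles <- ifelse(flip, "B/A", "A/B")  # major/minor after orientation

  set.seed(substream_seed(cfg$seed, 2L))
  quality <- matrix(runif(n * p, 0.7, 1), n, p)
  low <- matrix(runif(n * p) < cfg$low_quality_rate, n, p)
  quality[low] <- runif(sum(low), 0, 0.7)

  set.seed(substream_seed(cfg$seed, 3L))
  miss <- matrix(runif(n * p) < cfg$missing_call_rate, n, p)
  calls[miss] <- NA_integer_
  quality[miss] <- NA_real_

  snp_ids <- sprintf("snp%05d", seq_len(p))
  subj_ids <- sprintf("s%03d", seq_len(n))
  dimnames(calls) <- dimnames(quality) <- list(subj_ids, snp_ids)

  lay <- gene_layout(cfg)
  host <- ceiling(seq_len(p) / cfg$snps_per_gene)     # gene index per SNP
  within <- (seq_len(p) - 1L) %% cfg$snps_per_gene
  pos <- lay$start[host] + 1000L +
    as.integer(round(within * 18000 / max(1L, cfg$snps_per_gene - 1L)))

  list(
    genotypes = genotype_matrix(calls, quality, family),
    snp_map = data.frame(snp = snp_ids, chrom = "chr1", pos = pos,
                         alleles = alleles, gene = lay$gene[host],
                         stringsAsFactors = FALSE))
}

#' Construct a genotype matrix container
#'
#' @param calls integer matrix (subjects x SNPs) of minor-allele counts
#'   0/1/2 with NA for missing; dimnames required.
#' @param quality numeric matrix of per-call quality scores in \[0, 1\],
#'   same shape; must be NA exactly where calls are NA.
#' @param family optional factor of sibling-cluster labels per subject.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, quality = NULL, family = NULL) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)))
  if (ncol(calls) > 0L && is.null(colnames(calls)))
    stop("calls must have SNP ids as column names")
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("calls must be 0, 1, 2 or NA")
  if (is.null(quality)) {
    quality <- matrix(1, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    quality[is.na(calls)] <- NA_real_
  }
  stopifnot(identical(dim(quality), dim(calls)))
  if (any(is.na(quality) != is.na(calls)))
    stop("quality must be present exactly where calls are present")
  structure(list(calls = calls, quality = quality,
                 family = if (is.null(family)) factor(rownames(calls))
                          else as.factor(family)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Simulate the interaction network, neighborhood list and QTL table
#'
#' The gene graph is a stochastic block model over the layout's module
#' assignment. The micronutrient-neighborhood list is sampled so that
#' `neighborhood_frac` of it falls inside the first causal module. The planted
#' QTL phenotype receives intervals near `qtl_overlap_frac` of the causal
#' genes; remaining phenotypes get random intervals.
#'
#' @param cfg a [sim_config()].
#' @param annotation gene annotation; defaults to [gene_layout()].
#' @return list with `network` (igraph), `module_truth` (named integer vector,
#'   planted block per gene), `neighborhood_genes`, and `qtl_table`
#'   (phenotype, chrom, start, end, source; 1-based inclusive).
#' @export
simulate_network <- function(cfg, annotation = gene_layout(cfg)) {
  validate_sim_config(cfg)
  lay <- annotation
  n <- nrow(lay)
  set.seed(substream_seed(cfg$seed, 21L))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- lay$module[ij[, 1]] == lay$module[ij[, 2]]
  keep <- runif(nrow(ij)) < ifelse(same, cfg$sbm_p_in, cfg$sbm_p_out)
  edges <- data.frame(from = lay$gene[ij[keep, 1]],
                      to = lay$gene[ij[keep, 2]], stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = lay$gene)

  target <- cfg$causal_module_ids[1L]
  inside <- lay$gene[lay$module == target]
  outside <- lay$gene[lay$module != target]
  set.seed(substream_seed(cfg$seed, 22L))
  k_in <- min(length(inside), round(cfg$neighborhood_frac * cfg$n_neighborhood))
  nbr <- sort(c(sample(inside, k_in),
                sample(outside, cfg$n_neighborhood - k_in)))

  set.seed(substream_seed(cfg$seed, 23L))
  causal <- pick_causal_genes(cfg)
  span <- max(lay$end)
  phen <- c("body_weight", "serum_leptin", "serum_apoE", "serum_lipid",
            sprintf("qtl_pheno%02d", seq_len(max(0L, cfg$n_qtl_phenotypes - 4L)) + 4L))
  phen <- phen[seq_len(cfg$n_qtl_phenotypes)]
  planted <- phen[1L]
  rows <- list()
  n_cov <- max(1L, round(cfg$qtl_overlap_frac * length(causal)))
  covered <- if (length(causal)) causal[seq_len(min(n_cov, length(causal)))] else character(0)
  for (g in covered) {
    mid <- (lay$start[lay$gene == g] + lay$end[lay$gene == g]) / 2
    centre <- mid + round(runif(1, -8e5, 8e5))
    rows[[length(rows) + 1L]] <- data.frame(
      phenotype = planted, chrom = "chr1",
      start = max(1, round(centre - 1e5)), end = round(centre + 1e5),
      source = sprintf("QTL_%s_%02d", planted, length(rows) + 1L),
      stringsAsFactors = FALSE)
  }
  for (ph in phen[-1L]) {
    for (j in 1:3) {
      s <- round(runif(1, 1, span))
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, chrom = "chr1", start = s, end = s + 2e5,
        source = sprintf("QTL_%s_%02d", ph, j), stringsAsFactors = FALSE)
    }
  }
  qtl <- do.call(rbind, rows)

  list(network = net,
       module_truth = setNames(lay$module, lay$gene),
       neighborhood_genes = nbr,
       qtl_table = qtl)
}

#' Simulate covariates, metabolite assessments, proteins and the latent factor
#'
#' The latent factor is the standardized sum of the causal-SNP minor-allele
#' counts (weighted by `beta_snp`), small age and sex effects, and unit
#' Gaussian noise. Each metabolite is `loading * latent + N(0, noise_sd)` at
#' the subject level; three assessments per subject add
#' `N(0, assessment_sd_frac * noise_sd)` noise. Signal proteins carry
#' `protein_beta * latent` plus heavy-tailed t(3) noise on the log2 scale
#' (null proteins are pure t(3) noise); stored abundances are `2^log2value`.
#'
#' @param cfg a [sim_config()].
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param snp_map its SNP map (used to resolve causal genes to SNP columns).
#' @return list with `covariates`, `metabolites` (long data.frame:
#'   subject, assessment, metabolite, value), `proteins` (list: abundance
#'   matrix subjects x proteins, location annotation), and `truth`.
#' @export
simulate_phenotypes <- function(cfg, genotypes, snp_map) {
  validate_sim_config(cfg)
  causal_genes <- pick_causal_genes(cfg)
  causal_snps <- snp_map$snp[snp_map$gene %in% causal_genes]
  if (cfg$beta_snp != 0 && length(causal_snps) == 0L)
    stop("beta_snp is nonzero but no causal SNPs are resolvable")

  n <- nrow(genotypes$calls)
  subj <- rownames(genotypes$calls)
  set.seed(substream_seed(cfg$seed, 12L))
  age <- runif(n, 6, 14)
  sex <- rbinom(n, 1L, 0.5)
  hei <- pmin(95, pmax(10, rnorm(n, 55, 12)))

  gburden <- if (length(causal_snps)) {
    gc <- genotypes$calls[, causal_snps, drop = FALSE]
    # mean-impute the few missing calls for phenotype construction only
    mu <- colMeans(gc, na.rm = TRUE)
    nas <- which(is.na(gc), arr.ind = TRUE)
    if (nrow(nas)) gc[nas] <- mu[nas[, 2]]
    rowSums(gc) * cfg$beta_snp
  } else rep(0, n)
  latent <- as.numeric(scale(gburden +
                               cfg$gamma_age * as.numeric(scale(age)) +
                               cfg$gamma_sex * (sex - 0.5) + rnorm(n)))

  load <- cfg$metabolite_loadings
  k <- length(load)
  met_mean <- outer(latent, load) +
    matrix(rnorm(n * k, 0, cfg$noise_sd), n, k)
  colnames(met_mean) <- names(load)
  asd <- cfg$assessment_sd_frac * cfg$noise_sd
  panels <- lapply(1:3, function(a) {
    v <- met_mean + matrix(rnorm(n * k, 0, asd), n, k)
    data.frame(subject = rep(subj, k), assessment = a,
               metabolite = rep(names(load), each = n),
               value = as.numeric(v), stringsAsFactors = FALSE)
  })
  metabolites <- do.call(rbind, panels)

  set.seed(substream_seed(cfg$seed, 13L))
  prot_ids <- sprintf("prot%04d", seq_len(cfg$n_proteins))
  signal <- sort(sample(prot_ids, cfg$n_signal_proteins))
  logab <- matrix(rt(n * cfg$n_proteins, df = 3), n, cfg$n_proteins,
                  dimnames = list(subj, prot_ids))
  logab[, signal] <- logab[, signal] + cfg$protein_beta * latent
  location <- setNames(sample(c("plasma_membrane", "cytosolic"),
                              cfg$n_proteins, replace = TRUE,
                              prob = c(0.4, 0.6)), prot_ids)

  list(
    covariates = data.frame(subject = subj, age = age, sex = sex, hei = hei,
                            family = genotypes$family,
                            stringsAsFactors = FALSE),
    metabolites = metabolites,
    proteins = list(abundance = 2^logab, location = location),
    truth = list(latent = setNames(latent, subj),
                 metabolite_means = met_mean,
                 causal_genes = causal_genes, causal_snps = causal_snps,
                 causal_modules = cfg$causal_module_ids,
                 signal_proteins = signal))
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_genotypes()], [simulate_network()] and
#' [simulate_phenotypes()] under one root seed and assembles their outputs
#' plus the planted truth.
#'
#' @param cfg a [sim_config()].
#' @return A `synthetic_study` list: genotypes, snp_map, covariates,
#'   metabolites, proteins, network, gene_annotation, neighborhood_genes,
#'   qtl_table, truth.
#' @export
simulate_study <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  net <- simulate_network(cfg)
  phen <- simulate_phenotypes(cfg, geno$genotypes, geno$snp_map)
  truth <- phen$truth
  truth$module_truth <- net$module_truth
  truth$neighborhood_module <- cfg$causal_module_ids[1L]
  truth$planted_qtl_phenotype <- net$qtl_table$phenotype[1L]
  structure(list(
    config = cfg,
    genotypes = geno$genotypes, snp_map = geno$snp_map,
    covariates = phen$covariates, metabolites = phen$metabolites,
    proteins = phen$proteins,
    network = net$network,
    gene_annotation = gene_layout(cfg)[, c("gene", "chrom", "start", "end")],
    neighborhood_genes = net$neighborhood_genes,
    qtl_table = net$qtl_table,
    truth = truth), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_study: %d subjects, %d SNPs, %d-gene network (%d edges),\n",
    "  %d causal genes in module(s) %s, %d metabolites, %d proteins\n"),
    nrow(x$genotypes$calls), ncol(x$genotypes$calls),
    igraph::vcount(x$network), igraph::ecount(x$network),
    length(x$truth$causal_genes),
    paste(x$truth$causal_modules, collapse = ","),
    length(unique(x$metabolites$metabolite)),
    ncol(x$proteins$abundance)))
  invisible(x)
}
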