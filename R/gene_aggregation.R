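# Gene-level aggregation of SNP p-values with an LD-aware Monte-Carlo null:
# the gene statistic is the sum of 1-df chi-square quantiles of the member
# SNPs' nominal p-values, and its null distribution is simulated from a
# multivariate normal with the in-cohort genotype correlation matrix, so the
# gene p-value accounts for gene size, polymorphism, and local LD.

#' Build gene models (SNP membership + LD matrix) from positions
#'
#' A SNP belongs to every gene whose interval, extended by `flank` on both
#' sides, contains its position; the LD matrix is the Pearson correlation of
#' minor-allele counts in the supplied (post-QC) genotypes.
#'
#' @param snp_map data.frame: snp, chrom, pos (1-based).
#' @param annotation data.frame: gene, chrom, start, end (1-based inclusive;
#'   see [read_bed_genes()] for BED input). Duplicate gene ids are an error.
#' @param genotypes post-QC `genotype_matrix`; only SNPs present in it are
#'   assigned.
#' @param flank bp added to each side of every gene (default 50 kb, the
#'   gene-based-test convention; use 0 to restrict to gene bodies).
#' @return named list of `gene_model`s (gene, chrom, start, end, snps, R);
#'   genes with no member SNP are omitted and counted in attribute
#'   `n_empty`.
#' @export
build_gene_models <- function(snp_map, annotation, genotypes, flank = 50000) {
  if (anyDuplicated(annotation$gene))
    stop("duplicate gene ids in annotation")
  snps <- intersect(snp_map$snp, colnames(genotypes$calls))
  sm <- snp_map[match(snps, snp_map$snp), , drop = FALSE]
  snp_gr <- GenomicRanges::GRanges(sm$chrom,
                                   IRanges::IRanges(sm$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1L, annotation$start - as.integer(flank)),
                     annotation$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  by_gene <- split(sm$snp[S4Vectors::queryHits(hits)],
                   annotation$gene[S4Vectors::subjectHits(hits)])
  models <- lapply(names(by_gene), function(g) {
    ids <- by_gene[[g]]
    gcalls <- genotypes$calls[, ids, drop = FALSE]
    R <- suppressWarnings(cor(gcalls))
    # a post-QC constant column cannot arise, but a zero-variance pair would
    # yield NA; treat as uncorrelated rather than fail
    R[is.na(R)] <- 0
    diag(R) <- 1
    i <- match(g, annotation$gene)
    structure(list(gene = g, chrom = annotation$chrom[i],
                   start = annotation$start[i], end = annotation$end[i],
                   snps = ids, R = R), class = "gene_model")
  })
  names(models) <- names(by_gene)
  attr(models, "n_empty") <- nrow(annotation) - length(models)
  models
}

#' Gene statistic: sum of upper-tail chi-square(1) quantiles
#'
#' @param p nominal SNP p-values in (0, 1\]; zeros are clamped to the
#'   smallest positive double with a warning.
#' @return `sum(qchisq(1 - p, df = 1))`.
#' @export
gene_statistic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p == 0)) {
    warning("p = 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  sum(qchisq(p, df = 1, lower.tail = FALSE))
}

# eigenvalue-clipping PSD repair, diagonal rescaled to 1
repair_psd <- function(R, eps = 1e-8) {
  if (anyNA(R)) stop("LD matrix contains NA")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(e$values >= eps)) return(R)
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M / tcrossprod(d)
}

#' Monte-Carlo gene p-value under the LD-aware null
#'
#' Simulates `Z ~ MVN(0, R)` and compares `sum(Z^2)` with the observed
#' statistic, using the add-one estimator `p = (1 + #{null >= T}) / (1 + n)`.
#' The simulation schedule is adaptive: stages escalate while the current
#' estimate is below `10 / n_sims`, so small p-values get more simulations.
#'
#' @param T observed gene statistic from [gene_statistic()].
#' @param R LD (correlation) matrix of the member SNPs; repaired to positive
#'   semidefinite by eigenvalue clipping if needed.
#' @param stages increasing simulation sizes (default 1e3, 1e4, 1e6).
#' @param seed integer seed for this gene's simulations.
#' @return list: p, n_sims, T, n_snps.
#' @export
gene_pvalue <- function(T, R, stages = c(1e3, 1e4, 1e6), seed = 1L) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), T >= 0)
  k <- nrow(R)
  L <- chol(repair_psd(R) + diag(1e-10, k))
  set.seed(as.integer(seed))
  exceed <- 0; total <- 0
  for (ns in sort(stages)) {
    add <- ns - total
    if (add <= 0) next
    # simulate in manageable slabs to bound memory
    done <- 0
    while (done < add) {
      m <- min(add - done, 2e5)
      Z <- matrix(rnorm(m * k), m, k) %*% L
      exceed <- exceed + sum(rowSums(Z * Z) >= T)
      done <- done + m
    }
    total <- ns
    p <- (1 + exceed) / (1 + total)
    if (p >= 10 / total) break
  }
  list(p = (1 + exceed) / (1 + total), n_sims = total, T = T, n_snps = k)
}

#' Gene-level test over all gene models
#'
#' @param snp_results scan output from [run_genome_scan()] (uses `snp`, `p`).
#' @param gene_models list from [build_gene_models()].
#' @param stages simulation schedule passed to [gene_pvalue()].
#' @param seed root seed; each gene draws its own sub-seed from it.
#' @return data.frame: gene, n_snps, T, n_sims, p, q (BH over all genes with
#'   at least one tested SNP).
#' @export
run_gene_test <- function(snp_results, gene_models,
                          stages = c(1e3, 1e4, 1e6), seed = 1L) {
  pmap <- setNames(snp_results$p, snp_results$snp)
  rows <- lapply(seq_along(gene_models), function(i) {
    gm <- gene_models[[i]]
    keep <- gm$snps[gm$snps %in% names(pmap) & !is.na(pmap[gm$snps])]
    if (length(keep) == 0L) return(NULL)
    Tobs <- gene_statistic(pmap[keep])
    R <- gm$R[keep, keep, drop = FALSE]
    res <- gene_pvalue(Tobs, R, stages,
                       seed = substream_seed(seed, i))
    data.frame(gene = gm$gene, n_snps = length(keep), T = Tobs,
               n_sims = res$n_sims, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(0), n_snps = integer(0),
                      T = numeric(0), n_sims = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
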