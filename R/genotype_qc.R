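# SNP quality control: call quality, completeness, minor allele frequency,
# and an exact Hardy-Weinberg test, applied in that order. Each removed SNP is
# attributed to the first filter that removes it.

#' Remove SNPs with low-quality calls
#'
#' @param genotypes a `genotype_matrix`.
#' @param threshold quality-score cutoff (default 0.7).
#' @param mode `"any"` removes a SNP if any present call falls below the
#'   threshold (default, the strict reading for a fully-genotyped design);
#'   `"mean"` keys on the SNP's mean quality instead.
#' @return The filtered `genotype_matrix` with attribute `removed` (SNP ids).
#' @export
filter_quality <- function(genotypes, threshold = 0.7, mode = c("any", "mean")) {
  mode <- match.arg(mode)
  q <- genotypes$quality
  bad <- if (mode == "any") {
    apply(q, 2, function(col) any(col < threshold, na.rm = TRUE))
  } else {
    colMeans(q, na.rm = TRUE) < threshold
  }
  bad[is.na(bad)] <- FALSE
  .drop_snps(genotypes, bad)
}

#' Remove SNPs not genotyped in all subjects
#'
#' @param genotypes a `genotype_matrix`.
#' @return The filtered `genotype_matrix` with attribute `removed`.
#' @export
filter_completeness <- function(genotypes) {
  n_miss_subj <- rowSums(is.na(genotypes$calls))
  fully_missing <- n_miss_subj == ncol(genotypes$calls)
  if (any(fully_missing))
    message(sprintf("NOTE: %d subject(s) with no calls at all: %s",
                    sum(fully_missing),
                    paste(rownames(genotypes$calls)[fully_missing],
                          collapse = ", ")))
  bad <- colSums(is.na(genotypes$calls)) > 0L
  .drop_snps(genotypes, bad)
}

.drop_snps <- function(genotypes, bad) {
  out <- genotype_matrix(genotypes$calls[, !bad, drop = FALSE],
                         genotypes$quality[, !bad, drop = FALSE],
                         genotypes$family)
  attr(out, "removed") <- colnames(genotypes$calls)[bad]
  out
}

#' Minor allele frequency of a call vector
#'
#' @param calls integer vector of 0/1/2 calls (no missing values; run after
#'   the completeness filter).
#' @return `min(f, 1 - f)` where `f = sum(calls) / (2n)`.
#' @export
compute_maf <- function(calls) {
  if (length(calls) == 0L) stop("no calls")
  if (anyNA(calls)) stop("missing calls: apply the completeness filter first")
  f <- sum(calls) / (2 * length(calls))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of heterozygote counts whose conditional probability does not exceed that
#' of the observed count (two-sided). Monomorphic SNPs return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("no genotypes")
  n_a <- 2L * n_aa + n_Aa          # minor allele count (either orientation works)
  if (n_a > n) n_a <- 2L * n - n_a
  if (n_a == 0L) return(1)
  het <- seq.int(n_a %% 2L, n_a, by = 2L)  # admissible heterozygote counts
  # log P(n_Aa = h | allele counts): C(n, (n_a-h)/2, h, rest) * 2^h / C(2n, n_a)
  lp <- lchoose(n, (n_a - het) / 2) +
    lgamma(n - (n_a - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (n_a + het) / 2 + 1) +
    het * log(2) - lchoose(2 * n, n_a)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- min(n_Aa, n_a)
  min(1, sum(pr[pr <= pr[match(obs, het)] * (1 + 1e-7)]))
}

#' Run the full genotype QC cascade
#'
#' Filters in order: call quality (< `quality_threshold`), completeness
#' (any missing call), MAF (< `maf_threshold`), exact Hardy-Weinberg test
#' (p < `hwe_alpha`). The report attributes each removed SNP to the first
#' filter that removed it, so the removal counts plus the survivors partition
#' the input.
#'
#' @param genotypes a `genotype_matrix`.
#' @param quality_threshold per-call quality cutoff (default 0.7).
#' @param quality_mode see [filter_quality()].
#' @param maf_threshold minor-allele-frequency cutoff (default 0.1).
#' @param hwe_alpha Hardy-Weinberg significance level (default 0.001; an
#'   exact rather than chi-square test because cohorts may be small).
#' @return list with `genotypes` (survivors), and `report` (a `qc_report`:
#'   per-filter removal counts, survivor count, and a per-SNP table of MAF and
#'   HWE p for the SNPs reaching those filters).
#' @export
run_genotype_qc <- function(genotypes, quality_threshold = 0.7,
                            quality_mode = "any",
                            maf_threshold = 0.1, hwe_alpha = 0.001) {
  n_in <- ncol(genotypes$calls)
  g1 <- filter_quality(genotypes, quality_threshold, quality_mode)
  g2 <- filter_completeness(g1)
  maf <- apply(g2$calls, 2, compute_maf)
  g3 <- .drop_snps(g2, maf < maf_threshold)
  hwe_p <- apply(g3$calls, 2, function(v)
    hwe_exact_test(sum(v == 0L), sum(v == 1L), sum(v == 2L)))
  g4 <- .drop_snps(g3, hwe_p < hwe_alpha)
  report <- structure(list(
    n_input = n_in,
    removed = c(quality = length(attr(g1, "removed")),
                completeness = length(attr(g2, "removed")),
                maf = length(attr(g3, "removed")),
                hwe = length(attr(g4, "removed"))),
    n_surviving = ncol(g4$calls),
    snp_stats = data.frame(snp = names(maf), maf = maf,
                           hwe_p = hwe_p[match(names(maf), names(hwe_p))],
                           row.names = NULL, stringsAsFactors = FALSE),
    thresholds = c(quality = quality_threshold, maf = maf_threshold,
                   hwe_alpha = hwe_alpha)),
    class = "qc_report")
  stopifnot(sum(report$removed) + report$n_surviving == n_in)
  list(genotypes = g4, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "genotype QC: %d SNPs in -> %d out\n  removed: quality %d, completeness %d, MAF<%.2g %d, HWE p<%.2g %d\n",
    x$n_input, x$n_surviving, x$removed["quality"], x$removed["completeness"],
    x$thresholds["maf"], x$removed["maf"],
    x$thresholds["hwe_alpha"], x$removed["hwe"]))
  invisible(x)
}
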