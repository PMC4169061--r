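# Per-SNP association of the latent metabolite phenotype with genotype.
# Gaussian GEE with identity link and independence working correlation:
# point estimates coincide with OLS and inference uses the cluster-robust
# sandwich covariance over sibling clusters with the standard CR1
# small-sample adjustment, referenced against t with G - 1 degrees of
# freedom (G = number of clusters). With the tiny cluster counts this
# pipeline targets, the unadjusted sandwich z test is visibly
# anti-conservative; the adjusted t form holds its level.

#' Fit the clustered association model for one SNP
#'
#' @param phenotype numeric phenotype vector (met_PC1 scores).
#' @param genotype 0/1/2 minor-allele counts (additive coding) for the same
#'   subjects.
#' @param covariates data.frame with columns `age`, `sex`, `hei`.
#' @param clusters sibling-cluster labels (factor or character).
#' @param coding `"additive"` (default; 1-df Wald test on the allele-count
#'   slope against t with G - 1 degrees of freedom) or `"genotype"`
#'   (genotype classes as a factor; joint Wald F test on the class
#'   contrasts).
#' @return one-row data.frame: beta, se, z, p, n, coding. Under `"genotype"`
#'   coding beta/se/z refer to the heterozygote contrast and p to the joint
#'   test. A genotype that is constant in the analysed subjects yields NA
#'   statistics.
#' @export
fit_gee_snp <- function(phenotype, genotype, covariates, clusters,
                        coding = c("additive", "genotype")) {
  coding <- match.arg(coding)
  stopifnot(length(phenotype) == length(genotype),
            nrow(covariates) == length(phenotype))
  dat <- data.frame(y = phenotype, g = genotype,
                    age = covariates$age, sex = covariates$sex,
                    hei = covariates$hei, cl = as.factor(clusters))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  na_row <- data.frame(beta = NA_real_, se = NA_real_, z = NA_real_,
                       p = NA_real_, n = n, coding = coding,
                       stringsAsFactors = FALSE)
  if (n < 5L || length(unique(dat$g)) < 2L) return(na_row)

  if (coding == "genotype") dat$g <- factor(dat$g)
  fit <- lm(y ~ g + age + sex + hei, data = dat)
  gcoef <- grep("^g", names(coef(fit)), value = TRUE)
  if (anyNA(coef(fit)[gcoef])) return(na_row)

  n_cl <- length(unique(droplevels(dat$cl)))
  if (n_cl < 2L) {
    warning("fewer than 2 clusters: falling back to model-based SE")
    V <- vcov(fit)
    df <- n - length(coef(fit))
  } else {
    # CR1: HC1 residual scaling plus the G/(G-1) cluster adjustment
    V <- sandwich::vcovCL(fit, cluster = dat$cl, type = "HC1",
                          cadjust = TRUE)
    df <- n_cl - 1L
  }
  b <- coef(fit)[gcoef]
  if (coding == "additive") {
    se <- sqrt(V[gcoef, gcoef])
    z <- b / se
    data.frame(beta = unname(b), se = unname(se), z = unname(z),
               p = 2 * stats::pt(-abs(z), df), n = n, coding = coding,
               stringsAsFactors = FALSE)
  } else {
    Vg <- V[gcoef, gcoef, drop = FALSE]
    q <- length(b)
    stat <- drop(t(b) %*% solve(Vg, b)) / q
    se1 <- sqrt(Vg[1, 1])
    data.frame(beta = unname(b[1]), se = unname(se1),
               z = unname(b[1] / se1),
               p = stats::pf(stat, q, df, lower.tail = FALSE),
               n = n, coding = coding, stringsAsFactors = FALSE)
  }
}

#' Genome scan: the clustered model at every SNP plus BH correction
#'
#' @param phenotype named vector of met_PC1 scores (names are subject ids).
#' @param genotypes a `genotype_matrix` (post-QC).
#' @param covariates data.frame with subject, age, sex, hei, family.
#' @param coding see [fit_gee_snp()].
#' @return data.frame with one row per SNP: snp, beta, se, z, p, p_bh, n.
#'   SNPs are reported in the genotype matrix's column order; the BH
#'   adjustment is over all tested SNPs and is order-independent.
#' @export
run_genome_scan <- function(phenotype, genotypes, covariates,
                            coding = "additive") {
  snps <- colnames(genotypes$calls)
  if (length(snps) == 0L)
    return(data.frame(snp = character(0), beta = numeric(0), se = numeric(0),
                      z = numeric(0), p = numeric(0), p_bh = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  subj <- intersect(names(phenotype), covariates$subject)
  subj <- intersect(subj, rownames(genotypes$calls))
  if (length(subj) == 0L) stop("no subjects shared across inputs")
  y <- phenotype[subj]
  cov <- covariates[match(subj, covariates$subject), , drop = FALSE]
  calls <- genotypes$calls[subj, , drop = FALSE]

  res <- lapply(snps, function(s)
    fit_gee_snp(y, calls[, s], cov, cov$family, coding))
  out <- do.call(rbind, res)
  out <- data.frame(snp = snps, out[, c("beta", "se", "z", "p", "n")],
                    stringsAsFactors = FALSE)
  out$p_bh <- bh_adjust(out$p)
  out[, c("snp", "beta", "se", "z", "p", "p_bh", "n")]
}
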