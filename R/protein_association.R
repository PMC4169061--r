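# Robust association of plasma proteins with the latent metabolite phenotype,
# and two-way clustering of the significant set for heatmap display.

#' Huber M-estimation of a protein's slope on met_PC1
#'
#' M-estimation with Huber loss (tuning constant 1.345), MAD scale and
#' iteratively reweighted least squares (via [MASS::rlm()]; convergence
#' tolerance 1e-8, at most 200 iterations). The Wald p-value uses the robust
#' standard error against the standard normal.
#'
#' @param abundance protein values (already on the analysis scale).
#' @param scores met_PC1 scores for the same subjects.
#' @param psi `"huber"` (default) or `"bisquare"`.
#' @return one-row data.frame: slope, se, z, p, n. Zero-variance abundance
#'   yields NA statistics.
#' @export
robust_fit <- function(abundance, scores, psi = c("huber", "bisquare")) {
  psi <- match.arg(psi)
  ok <- !is.na(abundance) & !is.na(scores)
  x <- scores[ok]; y <- abundance[ok]
  if (length(y) < 10L) stop("need at least 10 complete pairs")
  if (sd(y) == 0 || sd(x) == 0)
    return(data.frame(slope = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, n = length(y)))
  psifun <- if (psi == "huber") MASS::psi.huber else MASS::psi.bisquare
  fit <- MASS::rlm(y ~ x, psi = psifun, scale.est = "MAD",
                   maxit = 200, acc = 1e-8)
  s <- summary(fit, method = "XtWX")$coefficients
  z <- s["x", "t value"]
  data.frame(slope = s["x", "Value"], se = s["x", "Std. Error"],
             z = z, p = 2 * pnorm(-abs(z)), n = length(y))
}

#' Robust protein screen against met_PC1 with two-way clustering
#'
#' Fits [robust_fit()] per protein, applies BH over all proteins, and
#' clusters the significant proteins by average linkage on correlation
#' distance (1 - Pearson r between protein profiles). The two top-level
#' dendrogram branches are reported; when a location annotation is supplied,
#' so is each branch's plasma/membrane fraction.
#'
#' @param panel subjects x proteins abundance matrix (row names are subject
#'   ids), or the `proteins` element of a `synthetic_study`.
#' @param met_pc a `met_pc` object or a named vector of met_PC1 scores.
#' @param log2_transform log2 the abundances first (default TRUE; aptamer
#'   panels are right-skewed).
#' @param q_threshold BH significance cutoff (default 0.1).
#' @param psi robust loss, see [robust_fit()].
#' @param location optional named vector ("plasma_membrane"/"cytosolic") per
#'   protein.
#' @return A `protein_screen` list: `results` (protein, slope, se, z, p, q,
#'   significant, r_sign), `branches` (list of protein-id vectors, NULL when
#'   fewer than 2 significant proteins), `branch_fractions`
#'   (plasma/membrane fraction per branch, if `location` given), `tree`.
#' @export
protein_screen <- function(panel, met_pc, log2_transform = TRUE,
                           q_threshold = 0.1, psi = "huber",
                           location = NULL) {
  if (is.list(panel) && !is.data.frame(panel)) {
    if (is.null(location)) location <- panel$location
    panel <- panel$abundance
  }
  scores <- if (inherits(met_pc, "met_pc")) met_pc1(met_pc) else met_pc
  subj <- intersect(rownames(panel), names(scores))
  if (length(subj) < 10L) stop("fewer than 10 joinable subjects")
  x <- panel[subj, , drop = FALSE]
  if (log2_transform) {
    if (any(x <= 0, na.rm = TRUE))
      stop("non-positive abundances: disable log2_transform")
    x <- log2(x)
  }
  s <- scores[subj]

  res <- do.call(rbind, lapply(colnames(x), function(pr)
    cbind(protein = pr, robust_fit(x[, pr], s, psi = psi))))
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$q) & res$q < q_threshold
  res$r_sign <- sign(vapply(colnames(x), function(pr)
    suppressWarnings(cor(x[, pr], s, use = "complete.obs")), numeric(1)))

  sig <- res$protein[res$significant]
  branches <- NULL; tree <- NULL; fractions <- NULL
  if (length(sig) >= 2L) {
    cm <- suppressWarnings(cor(x[, sig, drop = FALSE],
                               use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0; diag(cm) <- 1
    tree <- hclust(as.dist(1 - cm), method = "average")
    cut2 <- cutree(tree, k = min(2L, length(sig)))
    branches <- split(names(cut2), cut2)
    # order branches left-to-right as drawn
    first_leaf <- vapply(branches, function(b)
      min(match(b, tree$labels[tree$order])), numeric(1))
    branches <- branches[order(first_leaf)]
    names(branches) <- paste0("branch_", seq_along(branches))
    if (!is.null(location))
      fractions <- vapply(branches, function(b)
        mean(location[b] == "plasma_membrane", na.rm = TRUE), numeric(1))
  }
  structure(list(results = res, branches = branches,
                 branch_fractions = fractions, tree = tree,
                 q_threshold = q_threshold),
            class = "protein_screen")
}

#' @export
print.protein_screen <- function(x, ...) {
  cat(sprintf("protein_screen: %d proteins, %d significant at q < %.2g\n",
              nrow(x$results), sum(x$results$significant),
              x$q_threshold))
  if (!is.null(x$branch_fractions))
    cat(sprintf("  branch plasma/membrane fractions: %s\n",
                paste(sprintf("%.3f", x$branch_fractions), collapse = ", ")))
  invisible(x)
}

#' Plasma/membrane fraction of each top-level branch of a protein dendrogram
#'
#' @param branches list of protein-id vectors (e.g. from [protein_screen()]).
#' @param location named vector with values "plasma_membrane" or "cytosolic".
#' @return Numeric vector: fraction of plasma/membrane proteins per branch.
#' @export
branch_fractions <- function(branches, location) {
  vapply(branches, function(b)
    mean(location[b] == "plasma_membrane", na.rm = TRUE), numeric(1))
}
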