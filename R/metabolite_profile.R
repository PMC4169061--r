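# Latent metabolite phenotype: average repeated assessments, PCA, and
# hierarchical-clustering orders for heatmap display.

#' Average repeated metabolite assessments per subject
#'
#' @param panel long data.frame with columns subject, assessment, metabolite,
#'   value (missing values allowed).
#' @return numeric matrix subjects x metabolites of per-subject means over the
#'   available assessments; NA where a subject has no value for a metabolite.
#'   Subjects with no values at all are dropped with a warning.
#' @export
average_assessments <- function(panel) {
  stopifnot(all(c("subject", "metabolite", "value") %in% names(panel)))
  subjects <- unique(panel$subject)
  mets <- unique(panel$metabolite)
  ok <- !is.na(panel$value)
  m <- matrix(NA_real_, length(subjects), length(mets),
              dimnames = list(subjects, mets))
  if (any(ok)) {
    agg <- aggregate(value ~ subject + metabolite, data = panel[ok, ],
                     FUN = mean)
    m[cbind(match(agg$subject, subjects), match(agg$metabolite, mets))] <-
      agg$value
  }
  empty <- rowSums(!is.na(m)) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d subject(s) with no assessments: %s",
                    sum(empty), paste(head(subjects[empty], 5), collapse = ", ")))
    m <- m[!empty, , drop = FALSE]
  }
  m
}

#' Principal components of the averaged metabolite matrix
#'
#' Columns are z-scored by default (metabolites are on incommensurable assay
#' units), subjects with any missing metabolite are excluded (complete-case;
#' the cohorts this is designed for are too small to support imputation), and
#' the sign of component 1 is anchored so that the named anchor metabolite
#' loads non-negatively.
#'
#' @param m subjects x metabolites matrix from [average_assessments()].
#' @param standardize z-score columns before the eigen-decomposition.
#' @param anchor metabolite whose PC1 loading is forced `>= 0`.
#' @return A `met_pc` object: `scores` (subjects x components), `loadings`
#'   (unit-norm columns), `variance_explained` (fractions summing to 1),
#'   `anchor`, `n_used`.
#' @export
compute_met_pc <- function(m, standardize = TRUE, anchor = "vitamin_E") {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  cc <- complete.cases(m)
  x <- m[cc, , drop = FALSE]
  if (nrow(x) < 3L) stop("fewer than 3 complete cases")
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      stop("constant metabolite column(s): ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (!anchor %in% colnames(x))
    stop("anchor metabolite not present: ", anchor)
  if (pc$rotation[anchor, 1L] < 0) {
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
    pc$x[, 1L] <- -pc$x[, 1L]
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, anchor = anchor,
                 n_used = nrow(x)),
            class = "met_pc")
}

#' @export
print.met_pc <- function(x, ...) {
  cat(sprintf("met_pc: %d subjects, %d components; PC1 %.1f%%, PC2 %.1f%% (anchor: %s)\n",
              x$n_used, ncol(x$scores), 100 * x$variance_explained[1],
              100 * x$variance_explained[2], x$anchor))
  invisible(x)
}

#' Extract met_PC1 scores as a named vector
#' @param x a `met_pc` object.
#' @return named numeric vector of PC1 scores.
#' @export
met_pc1 <- function(x) {
  stopifnot(inherits(x, "met_pc"))
  setNames(x$scores[, 1L], rownames(x$scores))
}

#' Row and column orderings for a clustered heatmap
#'
#' Average-linkage hierarchical clustering on Euclidean distance of the
#' column-z-scored matrix, for both rows and columns.
#'
#' @param m complete numeric matrix.
#' @return list with `row_order`, `col_order` (integer leaf orders) and the
#'   two `hclust` trees (NULL when a dimension has < 2 entries, in which case
#'   the order is identity for rows, sort-by-value for a single column).
#' @export
cluster_heatmap_order <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  if (ncol(m) == 1L)
    return(list(row_order = order(m[, 1L]), col_order = 1L,
                row_tree = NULL, col_tree = NULL))
  z <- scale(m)
  z[, apply(m, 2, sd) == 0] <- 0
  ord <- function(x) {
    if (nrow(x) < 2L) return(list(order = seq_len(nrow(x)), tree = NULL))
    h <- hclust(dist(x), method = "average")
    list(order = h$order, tree = h)
  }
  r <- ord(z); co <- ord(t(z))
  list(row_order = r$order, col_order = co$order,
       row_tree = r$tree, col_tree = co$tree)
}
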