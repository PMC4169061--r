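# Hypergeometric overrepresentation machinery: network-module enrichment of
# gene sets, the dual "micronutrient system" criterion, QTL-window gene sets,
# and generic GMT sets.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: draws of size `n` from a
#' universe of `N` containing `K` marked elements.
#'
#' @param N universe size.
#' @param K marked (hit-set) size.
#' @param n drawn-unit (e.g. module) size.
#' @param k observed marked elements in the unit.
#' @return The exact upper-tail probability.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N || k > min(n, K))
    stop("require 0 <= k <= min(n, K) <= N")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.enrich_table <- function(units, hits, universe, unit_col = "unit") {
  hits <- unique(hits)
  dropped <- setdiff(hits, universe)
  hits <- intersect(hits, universe)
  N <- length(universe)
  K <- length(hits)
  if (K == 0L) warning("hit set has no members in the universe")
  rows <- lapply(names(units), function(u) {
    members <- intersect(unique(units[[u]]), universe)
    n <- length(members)
    k <- length(intersect(members, hits))
    data.frame(unit = u, universe_size = N, hit_set_size = K, unit_size = n,
               expected = n * K / N, observed = k,
               p = if (K == 0L) 1 else hypergeom_upper(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  names(out)[names(out) == "unit"] <- unit_col
  attr(out, "n_hits_dropped") <- length(dropped)
  out
}

#' Module enrichment of a gene set
#'
#' One upper-tail hypergeometric test per module, BH-corrected across the
#' modules of the partition (one family per analysis, never pooled).
#'
#' @param partition a `module_partition` from [spinglass_partition()].
#' @param gene_set character vector of hit genes; members outside the
#'   universe are dropped and counted in attribute `n_hits_dropped`.
#' @param universe gene universe (default: the partitioned nodes, i.e. the
#'   network's largest connected component).
#' @param q_threshold significance cutoff on the BH-adjusted p (default 0.1).
#' @return data.frame per module: module, universe_size, hit_set_size,
#'   unit_size, expected, observed, p, q, significant.
#' @export
module_enrichment <- function(partition, gene_set,
                              universe = names(partition$membership),
                              q_threshold = 0.1) {
  stopifnot(inherits(partition, "module_partition"))
  units <- split(names(partition$membership), partition$membership)
  names(units) <- paste0("module_", names(units))
  out <- .enrich_table(units, gene_set, universe, unit_col = "module")
  out$module <- as.integer(sub("^module_", "", out$module))
  out <- out[order(out$module), , drop = FALSE]
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Flag modules enriched in both the association hits and the neighborhood
#'
#' A "micronutrient system" is a module significant (q below the threshold)
#' in both the statistical (met_PC1 gene) and the knowledge-based
#' (micronutrient neighborhood) enrichment over the same partition.
#'
#' @param results_hits,results_neighborhood outputs of [module_enrichment()]
#'   on the same partition.
#' @param q_threshold cutoff applied to both analyses (default 0.1).
#' @return Integer vector of flagged module ids.
#' @export
micronutrient_system_flag <- function(results_hits, results_neighborhood,
                                      q_threshold = 0.1) {
  if (!identical(sort(results_hits$module),
                 sort(results_neighborhood$module)) ||
      !identical(results_hits$unit_size[order(results_hits$module)],
                 results_neighborhood$unit_size[order(results_neighborhood$module)]))
    stop("the two enrichment results are not over the same partition")
  a <- results_hits$module[results_hits$q < q_threshold]
  b <- results_neighborhood$module[results_neighborhood$q < q_threshold]
  sort(intersect(a, b))
}

#' Build QTL-window gene sets
#'
#' A gene belongs to a phenotype's set when its interval intersects any of
#' that phenotype's QTL intervals expanded by `window` bp on both sides.
#'
#' @param annotation data.frame: gene, chrom, start, end (1-based inclusive).
#' @param qtl_table data.frame: phenotype, chrom, start, end (1-based
#'   inclusive; see [read_bed_qtl()] for BED input).
#' @param window expansion in bp (default 1 Mbp).
#' @return Named list of gene-id vectors, one per phenotype with a nonempty
#'   set; phenotypes whose sets are empty are dropped with a warning.
#' @export
qtl_gene_sets <- function(annotation, qtl_table, window = 1e6) {
  gene_gr <- GenomicRanges::GRanges(annotation$chrom,
                                    IRanges::IRanges(annotation$start,
                                                     annotation$end))
  qtl_gr <- GenomicRanges::GRanges(
    qtl_table$chrom,
    IRanges::IRanges(pmax(1, qtl_table$start - window),
                     qtl_table$end + window))
  hits <- GenomicRanges::findOverlaps(gene_gr, qtl_gr)
  sets <- lapply(split(S4Vectors::queryHits(hits),
                       qtl_table$phenotype[S4Vectors::subjectHits(hits)]),
                 function(i) sort(unique(annotation$gene[i])))
  missing_ph <- setdiff(unique(qtl_table$phenotype), names(sets))
  if (length(missing_ph))
    warning("phenotype(s) with empty gene sets dropped: ",
            paste(missing_ph, collapse = ", "))
  sets
}

#' QTL-phenotype enrichment of significant genes
#'
#' @param significant_genes gene ids (e.g. genes with gene-level q < 0.1).
#' @param qtl_sets named list from [qtl_gene_sets()].
#' @param universe gene universe for the test.
#' @param q_threshold significance cutoff (default 0.15).
#' @return data.frame per phenotype with the enrichment columns and a
#'   `significant` flag.
#' @export
qtl_enrichment <- function(significant_genes, qtl_sets, universe,
                           q_threshold = 0.15) {
  out <- .enrich_table(qtl_sets, significant_genes, universe,
                       unit_col = "phenotype")
  out$significant <- out$q < q_threshold
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Overrepresentation of arbitrary GMT gene sets in a gene list
#'
#' @param gene_list hit genes.
#' @param gene_sets named list (e.g. from [read_gmt()]).
#' @param universe gene universe.
#' @param q_threshold BH significance cutoff (default 0.1).
#' @return data.frame, one row per set.
#' @export
gmt_enrichment <- function(gene_list, gene_sets, universe,
                           q_threshold = 0.1) {
  out <- .enrich_table(gene_sets, gene_list, universe, unit_col = "set")
  out$significant <- out$q < q_threshold
  out
}
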