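# End-to-end orchestration: simulate (or load) inputs, build the latent
# phenotype, QC the genotypes, scan SNPs, aggregate to genes, partition the
# network, test enrichment and QTL overlap, screen proteins, and record a
# reproducibility manifest.

#' Analysis parameters for the pipeline
#'
#' @param quality_threshold per-call quality cutoff (default 0.7).
#' @param maf_threshold MAF cutoff (default 0.1).
#' @param hwe_alpha Hardy-Weinberg exact-test level (default 0.001).
#' @param snp_alpha BH cutoff for significant SNPs (default 0.05).
#' @param gene_q BH cutoff for significant genes (default 0.1).
#' @param module_q BH cutoff for module enrichment (default 0.1).
#' @param qtl_q BH cutoff for QTL-phenotype enrichment (default 0.15).
#' @param protein_q BH cutoff for the protein screen (default 0.1).
#' @param flank gene-model flank in bp (default 50 kb).
#' @param qtl_window QTL window in bp (default 1 Mbp).
#' @param spins,gamma,cooling,tmin,restarts spin-glass settings, see
#'   [spinglass_partition()].
#' @param stages gene-test simulation schedule (pipeline default
#'   1e3/1e4/1e5: the smallest schedule that still resolves gene-level
#'   significance after BH at the default network size).
#' @param anchor PC1 sign-anchor metabolite.
#' @param coding genotype coding for the scan.
#' @param log2_proteins log2-transform protein abundances.
#' @param seed root seed for the stochastic stages.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(quality_threshold = 0.7, maf_threshold = 0.1,
                            hwe_alpha = 0.001, snp_alpha = 0.05,
                            gene_q = 0.1, module_q = 0.1, qtl_q = 0.15,
                            protein_q = 0.1, flank = 50000,
                            qtl_window = 1e6, spins = 100L, gamma = 1,
                            cooling = 0.99, tmin = 0.01, restarts = 5L,
                            stages = c(1e3, 1e4, 1e5),
                            anchor = "vitamin_E", coding = "additive",
                            log2_proteins = TRUE, seed = 1L) {
  stopifnot(quality_threshold >= 0, quality_threshold <= 1,
            maf_threshold >= 0, maf_threshold <= 0.5,
            hwe_alpha >= 0, hwe_alpha <= 1, snp_alpha >= 0, snp_alpha <= 1,
            gene_q >= 0, module_q >= 0, qtl_q >= 0, protein_q >= 0,
            flank >= 0, qtl_window >= 0, spins >= 2, restarts >= 1)
  as.list(environment())
}

#' Run the full analysis on an in-memory study
#'
#' Stages in dependency order: metabolite averaging + PCA; genotype QC; the
#' per-SNP clustered scan; gene models + LD-aware gene test; network LCC +
#' spin-glass modules; module enrichment for the significant genes and the
#' micronutrient neighborhood, plus the dual-enrichment flag; QTL-window
#' enrichment; protein screen.
#'
#' @param study a `synthetic_study` (or any list with the same input
#'   components).
#' @param params a [pipeline_params()] list.
#' @return A `micronet_analysis` list with every stage's output.
#' @export
analyze_study <- function(study, params = pipeline_params()) {
  met_mat <- average_assessments(study$metabolites)
  met_pc <- compute_met_pc(met_mat, anchor = params$anchor)

  qc <- run_genotype_qc(study$genotypes,
                        quality_threshold = params$quality_threshold,
                        maf_threshold = params$maf_threshold,
                        hwe_alpha = params$hwe_alpha)

  scan <- run_genome_scan(met_pc1(met_pc), qc$genotypes, study$covariates,
                          coding = params$coding)

  gene_models <- build_gene_models(study$snp_map, study$gene_annotation,
                                   qc$genotypes, flank = params$flank)
  genes <- run_gene_test(scan, gene_models, stages = params$stages,
                         seed = substream_seed(params$seed, 31L))
  sig_genes <- genes$gene[genes$q < params$gene_q]

  lcc <- largest_connected_component(study$network)
  partition <- spinglass_partition(lcc, q = params$spins,
                                   gamma = params$gamma,
                                   cooling = params$cooling,
                                   tmin = params$tmin,
                                   restarts = params$restarts,
                                   seed = substream_seed(params$seed, 32L))

  enrich_hits <- module_enrichment(partition, sig_genes,
                                   q_threshold = params$module_q)
  enrich_nbr <- module_enrichment(partition, study$neighborhood_genes,
                                  q_threshold = params$module_q)
  systems <- micronutrient_system_flag(enrich_hits, enrich_nbr,
                                       q_threshold = params$module_q)

  qtl_sets <- qtl_gene_sets(study$gene_annotation, study$qtl_table,
                            window = params$qtl_window)
  qtl <- qtl_enrichment(sig_genes, qtl_sets, universe = genes$gene,
                        q_threshold = params$qtl_q)

  proteins <- protein_screen(study$proteins, met_pc,
                             log2_transform = params$log2_proteins,
                             q_threshold = params$protein_q)

  structure(list(
    params = params, met_pc = met_pc, qc_report = qc$report,
    genotypes_qc = qc$genotypes, scan = scan, gene_models = gene_models,
    genes = genes, significant_genes = sig_genes, lcc = lcc,
    partition = partition, enrich_hits = enrich_hits,
    enrich_neighborhood = enrich_nbr, systems = systems,
    qtl_sets = qtl_sets, qtl = qtl, proteins = proteins),
    class = "micronet_analysis")
}

#' @export
print.micronet_analysis <- function(x, ...) {
  cat("micronet analysis\n")
  cat(sprintf("  met_PC1 variance explained: %.1f%%\n",
              100 * x$met_pc$variance_explained[1]))
  cat(sprintf("  SNPs after QC: %d; significant (BH < %.2g): %d\n",
              x$qc_report$n_surviving, x$params$snp_alpha,
              sum(x$scan$p_bh < x$params$snp_alpha, na.rm = TRUE)))
  cat(sprintf("  significant genes (q < %.2g): %d of %d tested\n",
              x$params$gene_q, length(x$significant_genes), nrow(x$genes)))
  cat(sprintf("  modules: %d; enriched in hits: %d, in neighborhood: %d; micronutrient systems: %s\n",
              length(x$partition$sizes),
              sum(x$enrich_hits$significant),
              sum(x$enrich_neighborhood$significant),
              if (length(x$systems)) paste(x$systems, collapse = ",") else "none"))
  cat(sprintf("  QTL phenotypes enriched (q < %.2g): %d\n", x$params$qtl_q,
              sum(x$qtl$significant)))
  cat(sprintf("  proteins significant (q < %.2g): %d of %d\n",
              x$params$protein_q, sum(x$proteins$results$significant),
              nrow(x$proteins$results)))
  invisible(x)
}

#' Cross-file consistency checks on study inputs
#'
#' @param study a study list (see [analyze_study()]).
#' @return data.frame of issues (empty when everything joins); columns
#'   check, n_affected, detail.
#' @export
validate_inputs <- function(study) {
  issues <- list()
  note <- function(check, ids) {
    if (length(ids))
      issues[[length(issues) + 1L]] <<- data.frame(
        check = check, n_affected = length(ids),
        detail = paste(head(ids, 5), collapse = ", "),
        stringsAsFactors = FALSE)
  }
  subj_g <- rownames(study$genotypes$calls)
  note("genotype subject missing from covariates",
       setdiff(subj_g, study$covariates$subject))
  note("metabolite subject missing from covariates",
       setdiff(unique(study$metabolites$subject), study$covariates$subject))
  note("protein subject missing from covariates",
       setdiff(rownames(study$proteins$abundance), study$covariates$subject))
  note("SNP map id missing from genotype matrix",
       setdiff(study$snp_map$snp, colnames(study$genotypes$calls)))
  net_genes <- igraph::V(study$network)$name
  note("network gene missing from annotation",
       setdiff(net_genes, study$gene_annotation$gene))
  note("neighborhood gene missing from network",
       setdiff(study$neighborhood_genes, net_genes))
  note("non-positive gene coordinates",
       study$gene_annotation$gene[study$gene_annotation$start < 1 |
                                    study$gene_annotation$end <
                                      study$gene_annotation$start])
  if (length(issues)) do.call(rbind, issues)
  else data.frame(check = character(0), n_affected = integer(0),
                  detail = character(0), stringsAsFactors = FALSE)
}

#' Run the pipeline end-to-end with file outputs and a manifest
#'
#' Simulates a synthetic study (or loads one from `input_dir`), writes the
#' inputs, runs [analyze_study()], writes every stage's table, and records a
#' manifest with the configuration hash and MD5 checksums of every file.
#' Re-running with the same configuration and seed reproduces identical
#' checksums.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] (used when `input_dir` is NULL).
#' @param params a [pipeline_params()]; its seed drives the stochastic
#'   stages.
#' @param input_dir optional directory of pre-existing inputs in
#'   [write_study()] layout.
#' @return list: `analysis` (the [analyze_study()] result) and `manifest`.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(),
                         params = pipeline_params(), input_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  completed <- character(0)
  manifest_path <- file.path(out_dir, "manifest.json")

  study <- if (is.null(input_dir)) simulate_study(sim) else read_study(input_dir)
  input_paths <- write_study(study, file.path(out_dir, "inputs"))
  completed <- c(completed, "inputs")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(sim = unclass(sim), params = params), cfg_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  issues <- validate_inputs(study)
  if (nrow(issues)) {
    message("input validation issues:")
    print(issues)
  }

  analysis <- tryCatch(analyze_study(study, params), error = function(e) {
    manifest <- list(status = "failed", error = conditionMessage(e),
                     completed_stages = completed,
                     checksums = as.list(tools::md5sum(unname(input_paths))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    stop(e)
  })
  completed <- c(completed, "analysis")

  p <- function(f) file.path(out_dir, f)
  .fwrite(data.frame(subject = rownames(analysis$met_pc$scores),
                     analysis$met_pc$scores[, 1:2, drop = FALSE]),
          p("met_pc_scores.csv"), ",")
  .fwrite(data.frame(metabolite = rownames(analysis$met_pc$loadings),
                     analysis$met_pc$loadings[, 1:2, drop = FALSE]),
          p("met_pc_loadings.csv"), ",")
  .fwrite(data.frame(component = seq_along(analysis$met_pc$variance_explained),
                     variance_fraction = analysis$met_pc$variance_explained),
          p("met_pc_variance.csv"), ",")
  .fwrite(analysis$qc_report$snp_stats, p("qc_snp_stats.tsv"), "\t")
  jsonlite::write_json(
    list(n_input = analysis$qc_report$n_input,
         removed = as.list(analysis$qc_report$removed),
         n_surviving = analysis$qc_report$n_surviving),
    p("qc_report.json"), auto_unbox = TRUE)
  .fwrite(analysis$scan, p("snp_scan.tsv"), "\t")
  .fwrite(analysis$genes, p("gene_results.tsv"), "\t")
  .fwrite(data.frame(gene = names(analysis$partition$membership),
                     module = unname(analysis$partition$membership)),
          p("module_partition.tsv"), "\t")
  .fwrite(analysis$enrich_hits, p("module_enrichment_hits.tsv"), "\t")
  .fwrite(analysis$enrich_neighborhood,
          p("module_enrichment_neighborhood.tsv"), "\t")
  writeLines(as.character(analysis$systems), p("micronutrient_systems.txt"))
  .fwrite(analysis$qtl, p("qtl_enrichment.tsv"), "\t")
  .fwrite(analysis$proteins$results, p("protein_results.tsv"), "\t")
  completed <- c(completed, "outputs")

  out_files <- c(cfg_path, unname(input_paths),
                 file.path(out_dir, c(
                   "met_pc_scores.csv", "met_pc_loadings.csv",
                   "met_pc_variance.csv", "qc_snp_stats.tsv",
                   "qc_report.json", "snp_scan.tsv", "gene_results.tsv",
                   "module_partition.tsv", "module_enrichment_hits.tsv",
                   "module_enrichment_neighborhood.tsv",
                   "micronutrient_systems.txt", "qtl_enrichment.tsv",
                   "protein_results.tsv")))
  sums <- tools::md5sum(out_files)
  names(sums) <- basename(out_files)
  manifest <- list(
    status = "complete",
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = params$seed,
    completed_stages = completed,
    checksums = as.list(sums),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("micronet")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  list(analysis = analysis, manifest = manifest)
}
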