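# Plain-text readers and writers for every pipeline input and output.
# Conventions: genotype calls and quality as TSV (subjects x SNPs, first
# column `subject`); SNP map / covariates / metabolites / proteins as
# CSV/TSV; gene and QTL intervals as BED (0-based half-open on disk,
# 1-based inclusive internally); networks as two-column edge TSV; gene sets
# as GMT or one-id-per-line text.

.fwrite <- function(x, path, sep) {
  data.table::fwrite(x, path, sep = sep)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' @param genotypes a `genotype_matrix`.
#' @param calls_path,quality_path output TSVs (quality optional on read).
#' @return the paths (write) or a `genotype_matrix` (read).
#' @export
write_genotypes <- function(genotypes, calls_path, quality_path = NULL) {
  df <- data.frame(subject = rownames(genotypes$calls), genotypes$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .fwrite(df, calls_path, "\t")
  if (!is.null(quality_path)) {
    qf <- data.frame(subject = rownames(genotypes$quality),
                     genotypes$quality, check.names = FALSE)
    .fwrite(qf, quality_path, "\t")
  }
  invisible(calls_path)
}

#' @rdname write_genotypes
#' @param family optional sibling-cluster factor per subject (read side).
#' @export
read_genotypes <- function(calls_path, quality_path = NULL, family = NULL) {
  df <- data.table::fread(calls_path, sep = "\t", data.table = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- df[[1]]
  quality <- NULL
  if (!is.null(quality_path)) {
    qf <- data.table::fread(quality_path, sep = "\t", data.table = FALSE)
    quality <- as.matrix(qf[, -1, drop = FALSE])
    rownames(quality) <- qf[[1]]
    quality <- quality[rownames(calls), colnames(calls), drop = FALSE]
  }
  genotype_matrix(calls, quality, family)
}

#' Read a metabolite panel (long or wide CSV; dialect autodetected)
#'
#' Long dialect has columns subject, assessment, metabolite, value; any
#' other header is treated as wide (first column subject ids, one column per
#' metabolite, single assessment).
#'
#' @param path CSV file.
#' @return Long data.frame: subject, assessment, metabolite, value.
#' @export
read_metabolites <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (all(c("subject", "metabolite", "value") %in% names(df))) {
    if (!"assessment" %in% names(df)) df$assessment <- 1L
    return(df[, c("subject", "assessment", "metabolite", "value")])
  }
  mets <- names(df)[-1]
  data.frame(subject = rep(df[[1]], length(mets)), assessment = 1L,
             metabolite = rep(mets, each = nrow(df)),
             value = unlist(df[mets], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read gene intervals from a BED-like file
#'
#' Columns: chrom, start, end, gene id (tab separated, BED convention:
#' 0-based half-open). Converted to 1-based inclusive internally.
#'
#' @param path BED file.
#' @return data.frame: gene, chrom, start, end (1-based inclusive).
#' @export
read_bed_genes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  data.frame(gene = df[[4]], chrom = df[[1]], start = df[[2]] + 1L,
             end = df[[3]], stringsAsFactors = FALSE)
}

#' Write gene intervals as BED (0-based half-open)
#' @param annotation data.frame gene, chrom, start, end (1-based inclusive).
#' @param path output file.
#' @export
write_bed_genes <- function(annotation, path) {
  data.table::fwrite(data.frame(annotation$chrom, annotation$start - 1L,
                                annotation$end, annotation$gene),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write phenotype-labelled QTL intervals (BED-like)
#'
#' Columns: chrom, start, end, phenotype, source id (BED 0-based half-open
#' on disk).
#'
#' @param path file path.
#' @return data.frame: phenotype, chrom, start, end, source (1-based).
#' @export
read_bed_qtl <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  out <- data.frame(phenotype = df[[4]], chrom = df[[1]],
                    start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  out$source <- if (ncol(df) >= 5) df[[5]] else sprintf("qtl%04d", seq_len(nrow(df)))
  out
}

#' @rdname read_bed_qtl
#' @param qtl_table internal QTL table (1-based inclusive).
#' @export
write_bed_qtl <- function(qtl_table, path) {
  data.table::fwrite(data.frame(qtl_table$chrom, qtl_table$start - 1L,
                                qtl_table$end, qtl_table$phenotype,
                                qtl_table$source),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic study to a directory of plain-text files
#'
#' Emits every downstream input format: genotype + quality TSV, SNP map TSV,
#' covariates CSV, metabolite CSV (long), protein CSV + location CSV,
#' edge-list TSV, gene and QTL BED files, neighborhood gene list, and the
#' planted truth as JSON.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_genotypes(study$genotypes, p("genotypes.tsv"), p("genotype_quality.tsv"))
  .fwrite(study$snp_map, p("snp_map.tsv"), "\t")
  .fwrite(study$covariates, p("covariates.csv"), ",")
  .fwrite(study$metabolites, p("metabolites.csv"), ",")
  prot <- data.frame(subject = rownames(study$proteins$abundance),
                     study$proteins$abundance, check.names = FALSE)
  .fwrite(prot, p("proteins.csv"), ",")
  .fwrite(data.frame(protein = names(study$proteins$location),
                     location = unname(study$proteins$location)),
          p("protein_location.csv"), ",")
  el <- igraph::as_edgelist(study$network)
  .fwrite(data.frame(from = el[, 1], to = el[, 2]), p("network_edges.tsv"), "\t")
  write_bed_genes(study$gene_annotation, p("genes.bed"))
  write_bed_qtl(study$qtl_table, p("qtl.bed"))
  writeLines(study$neighborhood_genes, p("neighborhood_genes.txt"))
  truth <- study$truth
  truth$latent <- as.list(truth$latent)
  truth$metabolite_means <- NULL
  truth$module_truth <- as.list(truth$module_truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("genotypes.tsv", "genotype_quality.tsv", "snp_map.tsv",
             "covariates.csv", "metabolites.csv", "proteins.csv",
             "protein_location.csv", "network_edges.tsv", "genes.bed",
             "qtl.bed", "neighborhood_genes.txt", "truth.json")
  invisible(setNames(file.path(dir, files), files))
}

#' Read study inputs back from a directory written by [write_study()]
#'
#' @param dir input directory.
#' @return A list with the same input components as a `synthetic_study`
#'   (truth included when `truth.json` is present).
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  covariates <- data.table::fread(p("covariates.csv"), data.table = FALSE)
  covariates$family <- factor(covariates$family)
  genotypes <- read_genotypes(p("genotypes.tsv"), p("genotype_quality.tsv"))
  genotypes$family <- covariates$family[
    match(rownames(genotypes$calls), covariates$subject)]
  prot <- data.table::fread(p("proteins.csv"), data.table = FALSE)
  ab <- as.matrix(prot[, -1, drop = FALSE]); rownames(ab) <- prot[[1]]
  loc <- data.table::fread(p("protein_location.csv"), data.table = FALSE)
  edges <- data.table::fread(p("network_edges.tsv"), data.table = FALSE)
  out <- list(
    genotypes = genotypes,
    snp_map = data.table::fread(p("snp_map.tsv"), data.table = FALSE),
    covariates = covariates,
    metabolites = read_metabolites(p("metabolites.csv")),
    proteins = list(abundance = ab,
                    location = setNames(loc$location, loc$protein)),
    network = load_network(edges),
    gene_annotation = read_bed_genes(p("genes.bed")),
    neighborhood_genes = readLines(p("neighborhood_genes.txt")),
    qtl_table = read_bed_qtl(p("qtl.bed")))
  if (file.exists(p("truth.json")))
    out$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  structure(out, class = "synthetic_study")
}
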