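# Plain-text interchange: feature-by-sample matrices as TSV (first column
# the feature ID), CpG positions as BED (0-based half-open), gene and SNP
# annotation as TSV, truth registry and config as JSON.

#' Write / read a feature-by-sample matrix as TSV
#'
#' Features in rows, samples in columns; the first column (`feature_id`)
#' carries the row names. `read_matrix_tsv` restores the numeric matrix and
#' optionally tags it with a layer.
#'
#' @param x matrix with row and column names.
#' @param path output / input file.
#' @param layer optional layer tag applied on read (see [omics_matrix()]).
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   the matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  d <- data.frame(feature_id = rownames(x), unclass_matrix(as_values(x)),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, layer = NULL) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (!is.null(layer)) m <- omics_matrix(m, layer)
  m
}

#' Write the synthetic dataset to a directory of text files
#'
#' Methylation, counts and genotypes as matrix TSVs; covariates as TSV with
#' header; CpG positions as BED (0-based half-open) plus a feature-flag
#' TSV; gene and SNP annotation as TSV; traits as TSV; truth registry and
#' configuration as JSON.
#'
#' @param dataset an `eqtm_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eqtm_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(dataset$methylation, p("methylation.tsv"))
  write_matrix_tsv(dataset$counts, p("counts.tsv"))
  write_matrix_tsv(dataset$genotypes, p("genotypes.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(dataset$covariates),
               dataset$covariates, check.names = FALSE),
    p("covariates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cpgs <- dataset$annotations$cpgs
  bed <- data.frame(chrom = cpgs$chrom, start = cpgs$position - 1L,
                    end = cpgs$position, name = cpgs$cpg_id)
  utils::write.table(bed, p("cpgs.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cpgs, p("cpg_features.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$annotations$genes, p("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$annotations$snps, p("snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(dataset$traits) > 0) {
    tr <- data.frame(sample_id = colnames(dataset$methylation),
                     dataset$traits, check.names = FALSE)
    utils::write.table(tr, p("traits.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(dataset$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(unclass(dataset$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an eQTM catalog as TSV
#'
#' One row per retained CpG-transcript pair with positions, distance,
#' relation, effect, test statistics and a lead-pair flag. Infinite
#' (inter-chromosomal) distances are written as `Inf`.
#'
#' @param catalog an `eqtm_catalog`.
#' @param annotations `feature_annotation` supplying positions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, annotations, path) {
  pairs <- catalog$pairs
  ci <- match(pairs$cpg_id, annotations$cpgs$cpg_id)
  gi <- match(pairs$gene_id, annotations$genes$gene_id)
  lead_key <- paste(catalog$lead$cpg_id, catalog$lead$gene_id)
  out <- data.frame(
    cpg_id = pairs$cpg_id, gene_id = pairs$gene_id,
    chrom_cpg = annotations$cpgs$chrom[ci],
    pos_cpg = annotations$cpgs$position[ci],
    chrom_gene = annotations$genes$chrom[gi],
    tss = annotations$genes$tss[gi],
    distance_bp = pairs$distance_bp, relation = pairs$relation,
    beta = pairs$beta, se = pairs$se, t = pairs$t_stat, p = pairs$p_value,
    is_lead = paste(pairs$cpg_id, pairs$gene_id) %in% lead_key,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read summary statistics as TSV
#'
#' Columns: snp_id, chrom, pos(ition), ea, oa, beta, se, p, maf, n.
#'
#' @param stats a `summary_stats` data.frame.
#' @param path file path.
#' @return `path` invisibly / the `summary_stats` data.frame.
#' @export
write_summary_stats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats_tsv
#' @export
read_summary_stats_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "beta", "se", "ea", "oa")
  if (!all(need %in% names(d)))
    stop("summary stats need columns: ", paste(need, collapse = ", "))
  class(d) <- c("summary_stats", class(d))
  d
}
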