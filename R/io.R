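#' Write and read the pipeline's TSV formats
#'
#' Genotypes are written with SNPs as rows and samples as columns (values
#' 0/1/2/NA); expression with probes as rows and samples as columns.
#' Annotations are one row per SNP or probe. All positions are 1-based.
#'
#' @param panel A [genotype_panel()] or [expression_panel()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, `"genotypes"`/`"expression"`.
#' @return Invisibly, the paths written.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_genotype_tsv <- function(panel, dir, prefix = "genotypes") {
  stopifnot(inherits(panel, "genotype_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, paste0(prefix, ".tsv"))
  apath <- file.path(dir, paste0(prefix, "_snps.tsv"))
  as_tibble(t(panel$genotypes), rownames = "snp_id") |>
    readr::write_tsv(gpath)
  readr::write_tsv(panel$snps, apath)
  invisible(c(gpath, apath))
}

#' @rdname panel_io
#' @export
write_expression_tsv <- function(panel, dir, prefix = "expression") {
  stopifnot(inherits(panel, "expression_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  epath <- file.path(dir, paste0(prefix, ".tsv"))
  apath <- file.path(dir, paste0(prefix, "_probes.tsv"))
  as_tibble(t(panel$values), rownames = "probe_id") |>
    readr::write_tsv(epath)
  readr::write_tsv(panel$probes, apath)
  invisible(c(epath, apath))
}

#' Read a genotype panel from TSV files
#'
#' @param genotype_tsv TSV with SNPs as rows (`snp_id` first column) and
#'   samples as columns.
#' @param snp_tsv SNP annotation TSV (`snp_id`, `chrom`, `pos`, ...).
#' @return A [genotype_panel()].
#' @export
read_genotype_panel <- function(genotype_tsv, snp_tsv) {
  g <- readr::read_tsv(genotype_tsv, show_col_types = FALSE)
  snps <- readr::read_tsv(snp_tsv, show_col_types = FALSE,
                          col_types = readr::cols(chrom = "c"))
  mat <- t(as.matrix(g[, -1]))
  colnames(mat) <- g[[1]]
  snps <- snps[match(colnames(mat), snps$snp_id), ]
  genotype_panel(mat, snps)
}

#' Read an expression panel from TSV files
#'
#' @param expression_tsv TSV with probes as rows (`probe_id` first column)
#'   and samples as columns.
#' @param probe_tsv Probe annotation TSV (`probe_id`, `chrom`, `midpoint`,
#'   ...).
#' @param state Normalization state of the stored values.
#' @return An [expression_panel()].
#' @export
read_expression_panel <- function(expression_tsv, probe_tsv, state = "raw") {
  e <- readr::read_tsv(expression_tsv, show_col_types = FALSE)
  probes <- readr::read_tsv(probe_tsv, show_col_types = FALSE,
                            col_types = readr::cols(chrom = "c"))
  mat <- t(as.matrix(e[, -1]))
  colnames(mat) <- e[[1]]
  probes <- probes[match(colnames(mat), probes$probe_id), ]
  expression_panel(mat, probes, state = state)
}
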