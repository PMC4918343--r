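#' Genotype panel: allele-count matrix plus SNP annotation
#'
#' Container for array-style genotypes coded as allele counts (0 or 2 for the
#' homozygous genotypes, 1 for heterozygotes; `NA` for missing calls), with a
#' per-SNP annotation table. Samples are rows, SNPs are columns.
#'
#' @param genotypes Numeric matrix, samples x SNPs, values in `{0, 1, 2, NA}`.
#'   Row names are sample ids, column names are SNP ids.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   and optionally `ref`, `alt`. One row per column of `genotypes`, same
#'   order.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes` (matrix) and `snps` (tibble).
#' @export
#' @examples
#' g <- matrix(c(0, 1, 2, 0), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("rs1", "rs2")))
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100, 200))
#' genotype_panel(g, snps)
genotype_panel <- function(genotypes, snps) {
  stopifnot(is.matrix(genotypes))
  snps <- as_tibble(snps)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps))) {
    abort("`snps` needs columns snp_id, chrom, pos")
  }
  vals <- genotypes[!is.na(genotypes)]
  if (!all(vals %in% c(0, 1, 2))) {
    abort("genotype values must be 0, 1, 2 or NA (allele counts)")
  }
  if (anyDuplicated(snps$snp_id)) abort("SNP ids must be unique")
  if (any(snps$pos < 0)) abort("SNP positions must be non-negative")
  if (ncol(genotypes) != nrow(snps)) {
    abort("one annotation row per genotype column required")
  }
  if (is.null(colnames(genotypes))) colnames(genotypes) <- snps$snp_id
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("sample_", seq_len(nrow(genotypes)))
  }
  if (!identical(colnames(genotypes), as.character(snps$snp_id))) {
    abort("genotype column names must match snps$snp_id in order")
  }
  structure(list(genotypes = genotypes, snps = snps),
            class = "genotype_panel")
}

#' Expression panel: intensity matrix plus probe annotation
#'
#' Container for microarray expression values with probe annotation and a
#' normalization-state tag. Samples are rows, probes are columns.
#'
#' @param values Numeric matrix, samples x probes. Row names are sample ids,
#'   column names probe ids.
#' @param probes Data frame with columns `probe_id`, `chrom`, `midpoint`
#'   (1-based bp), and optionally `gene_symbol`, `has_common_snp`,
#'   `detected_fraction`.
#' @param state Normalization state: `"raw"` (intensities, positive),
#'   `"log2"` (log2 scale, no quantile normalization) or `"quantile_log2"`
#'   (quantile normalized then log2 transformed).
#'
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, probes,
                             state = c("raw", "log2", "quantile_log2")) {
  state <- match.arg(state)
  stopifnot(is.matrix(values))
  probes <- as_tibble(probes)
  if (!all(c("probe_id", "chrom", "midpoint") %in% names(probes))) {
    abort("`probes` needs columns probe_id, chrom, midpoint")
  }
  if (anyDuplicated(probes$probe_id)) abort("probe ids must be unique")
  if (ncol(values) != nrow(probes)) {
    abort("one annotation row per expression column required")
  }
  if (is.null(colnames(values))) colnames(values) <- probes$probe_id
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (!identical(colnames(values), as.character(probes$probe_id))) {
    abort("expression column names must match probes$probe_id in order")
  }
  structure(list(values = values, probes = probes, state = state),
            class = "expression_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs, %.2f%% missing\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d samples x %d probes [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Tidy a genotype panel into a long tibble
#'
#' @param x A [genotype_panel()].
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `snp_id`, `genotype`.
#' @export
tidy.genotype_panel <- function(x, ...) {
  as_tibble(x$genotypes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "snp_id",
                        values_to = "genotype")
}

#' Tidy an expression panel into a long tibble
#'
#' @param x An [expression_panel()].
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `probe_id`, `value`.
#' @export
tidy.expression_panel <- function(x, ...) {
  as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "probe_id",
                        values_to = "value")
}
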