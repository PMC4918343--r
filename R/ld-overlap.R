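#' Genotypic r-squared between two SNPs
#'
#' Squared Pearson correlation of allele-count vectors over
#' pairwise-complete samples (composite/genotypic LD, the standard proxy for
#' haplotype r-squared when phase is unavailable). Invariant to allele-label
#' flips (`g -> 2 - g`).
#'
#' @param g1,g2 Numeric allele-count vectors (0/1/2, `NA` missing), equal
#'   length.
#' @return A fraction in \[0, 1\], or `NA` when either vector is constant on
#'   the complete samples (undefined LD, treated as below any threshold).
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) abort("vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) abort("need at least 3 pairwise-complete samples")
  a <- g1[ok]; b <- g2[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Pairwise genotypic r-squared matrix for a SNP panel
#'
#' @param genotypes A [genotype_panel()] or a samples x SNPs allele-count
#'   matrix with column names.
#' @return Symmetric matrix of squared Pearson correlations
#'   (pairwise-complete samples), unit diagonal; `NA` where LD is undefined.
#' @export
ld_matrix <- function(genotypes) {
  g <- if (inherits(genotypes, "genotype_panel")) genotypes$genotypes
       else genotypes
  stopifnot(is.matrix(g), !is.null(colnames(g)))
  r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  r2
}

#' Expand a SNP set by LD proxies
#'
#' Adds to the seed set every SNP in the matrix whose r-squared with at
#' least one seed SNP exceeds the threshold. A single hop only: proxies of
#' proxies are not pulled in (no transitive closure), matching tagSNP usage.
#' Undefined (`NA`) LD never qualifies.
#'
#' @param seed_snps Character vector of seed SNP ids (each present in `ld`).
#' @param ld Square r-squared matrix with SNP ids as dimnames, as from
#'   [ld_matrix()].
#' @param threshold LD threshold. Default 0.8.
#' @param strict Use `r2 > threshold` (default, "exceeding"); `FALSE` uses
#'   `>=`.
#' @return Character vector: seed SNPs plus their proxies, in matrix order.
#' @export
expand_by_ld <- function(seed_snps, ld, threshold = 0.8, strict = TRUE) {
  if (length(seed_snps) == 0) return(character())
  absent <- setdiff(seed_snps, rownames(ld))
  if (length(absent)) {
    abort(sprintf("seed SNP(s) absent from LD matrix: %s",
                  paste(utils::head(absent, 5), collapse = ", ")))
  }
  block <- ld[seed_snps, , drop = FALSE]
  hit <- if (strict) block > threshold else block >= threshold
  hit[is.na(hit)] <- FALSE
  proxies <- colnames(ld)[colSums(hit) > 0]
  rownames(ld)[rownames(ld) %in% union(seed_snps, proxies)]
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing an overlap at least as large as `overlap`
#' between a set of size `set_a` and a set of size `set_b` drawn without
#' replacement from a universe of size `universe`; computed in log space so
#' extreme enrichments do not underflow before exponentiation.
#'
#' @param overlap Observed overlap count.
#' @param set_a,set_b Sizes of the two sets.
#' @param universe Universe size.
#' @return `P(X >= overlap)` for `X ~ Hypergeometric(universe, set_a,
#'   set_b)`; 1 when `overlap` is 0.
#' @export
#' @examples
#' hypergeom_enrichment(5, 5, 5, 10) # 1 / choose(10, 5)
hypergeom_enrichment <- function(overlap, set_a, set_b, universe) {
  if (any(c(overlap, set_a, set_b, universe) < 0) ||
      overlap > min(set_a, set_b) || max(set_a, set_b) > universe) {
    abort("need overlap <= min(set_a, set_b) <= universe")
  }
  exp(stats::phyper(overlap - 1, set_a, universe - set_a, set_b,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Partition eQTL probes by sharing with two external datasets
#'
#' A probe's eQTL is "shared" with an external dataset when that dataset
#' reports an eQTL for the same gene (or probe) whose SNP is identical to,
#' or in LD (`r2 >= threshold`) with, the probe's SNP. Probes are
#' partitioned into found-in-all-three / also-in-dataset-b /
#' also-in-dataset-c / unique, with percentages of the total.
#'
#' @param our_eqtls Tibble of this study's significant eQTLs: `probe_id`,
#'   `snp_id` and (for gene matching) `gene_symbol`. One row per
#'   probe-SNP pair; a probe is shared if any of its pairs matches.
#' @param dataset_b,dataset_c External eQTL tables with `snp_id` and the
#'   matching key column.
#' @param ld Optional r-squared matrix covering the SNPs involved; SNP pairs
#'   absent from it only match by identity.
#' @param threshold LD threshold (inclusive). Default 0.8.
#' @param by Matching key: `"gene_symbol"` (default, for external lists) or
#'   `"probe_id"`.
#' @param labels Names of the two external datasets, used in the partition
#'   labels.
#' @return An `overlap_report`; see [overlap_report()].
#' @export
share_across_datasets <- function(our_eqtls, dataset_b, dataset_c, ld = NULL,
                                  threshold = 0.8,
                                  by = c("gene_symbol", "probe_id"),
                                  labels = c("monocytes", "bcells")) {
  by <- match.arg(by)
  our_eqtls <- as_tibble(our_eqtls)
  if (!all(c(by, "snp_id", "probe_id") %in% names(our_eqtls))) {
    abort(sprintf("our_eqtls needs columns probe_id, snp_id, %s", by))
  }
  shared_with <- function(ext) {
    ext <- as_tibble(ext)
    if (nrow(ext) == 0) return(character())
    if (!all(c(by, "snp_id") %in% names(ext))) {
      abort(sprintf("external dataset needs columns snp_id, %s", by))
    }
    hits <- our_eqtls |>
      inner_join(ext |> select(dplyr::all_of(c(by, "snp_id"))) |>
                   rename(ext_snp = "snp_id"),
                 by = by, relationship = "many-to-many") |>
      mutate(match = .data$snp_id == .data$ext_snp |
               pair_ld(.data$snp_id, .data$ext_snp, ld) >= threshold) |>
      filter(.data$match)
    unique(hits$probe_id)
  }
  in_b <- shared_with(dataset_b)
  in_c <- shared_with(dataset_c)
  probes <- unique(our_eqtls$probe_id)
  counts <- c(
    all_three = sum(probes %in% in_b & probes %in% in_c),
    b_only = sum(probes %in% in_b & !(probes %in% in_c)),
    c_only = sum(!(probes %in% in_b) & probes %in% in_c),
    unique = sum(!(probes %in% in_b) & !(probes %in% in_c))
  )
  overlap_report(counts["all_three"], counts["b_only"], counts["c_only"],
                 counts["unique"], labels = labels)
}

# vectorized r2 lookup; pairs absent from the matrix get NA -> no LD match
pair_ld <- function(s1, s2, ld) {
  if (is.null(ld)) return(rep(NA_real_, length(s1)))
  out <- rep(NA_real_, length(s1))
  ok <- s1 %in% rownames(ld) & s2 %in% colnames(ld)
  out[ok] <- ld[cbind(s1[ok], s2[ok])]
  out
}

#' Venn partition report for cross-dataset eQTL sharing
#'
#' Builds the four-way partition (all three subsets / shared with the first
#' external dataset only / shared with the second only / unique to this
#' study) with percentages of the total, rounded half-even to 2 decimals.
#'
#' @param all_three,b_only,c_only,unique_only Partition counts.
#' @param labels Names of the two external datasets.
#' @return An `overlap_report`: list with `partition` tibble (`category`,
#'   `count`, `percent`) and `total`.
#' @export
#' @examples
#' overlap_report(248, 159, 28, 536)
overlap_report <- function(all_three, b_only, c_only, unique_only,
                           labels = c("monocytes", "bcells")) {
  counts <- c(all_three, b_only, c_only, unique_only)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  partition <- tibble(
    category = c("all_three", paste0("with_", labels[1], "_only"),
                 paste0("with_", labels[2], "_only"), "unique"),
    count = as.integer(counts),
    percent = unname(format_percent(counts, total))
  )
  structure(list(partition = partition, total = total, labels = labels),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d probes\n", x$total))
  print(x$partition)
  invisible(x)
}

#' Tidy the Venn partition of an overlap report
#'
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @return The partition tibble (`category`, `count`, `percent`).
#' @export
tidy.overlap_report <- function(x, ...) x$partition

#' One-row summary of an overlap report
#'
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @return One-row tibble with the total, the four partition counts, and
#'   the derived per-dataset shared counts (all_three + dataset-only).
#' @export
glance.overlap_report <- function(x, ...) {
  p <- x$partition$count
  tibble(
    total = x$total, all_three = p[1],
    !!paste0("with_", x$labels[1], "_only") := p[2],
    !!paste0("with_", x$labels[2], "_only") := p[3],
    unique = p[4],
    !!paste0("shared_with_", x$labels[1]) := p[1] + p[2],
    !!paste0("shared_with_", x$labels[2]) := p[1] + p[3]
  )
}

#' Bar chart of an overlap report's Venn partition
#'
#' @param object An `overlap_report`.
#' @param ... Unused.
#' @return A ggplot of counts per partition category, labelled with
#'   percentages.
#' @export
autoplot.overlap_report <- function(object, ...) {
  d <- object$partition |>
    mutate(category = factor(.data$category, levels = .data$category))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "probes") +
    ggplot2::theme_minimal()
}

#' Intersect an LD-expanded eQTL SNP set with a GWAS catalog
#'
#' For each trait in the catalog, counts the catalog SNPs that fall in the
#' expanded eQTL SNP set and computes the hypergeometric enrichment of the
#' overlap against the catalog SNP universe. Malformed catalog rows
#' (missing SNP or trait) are skipped with a warning.
#'
#' @param expanded_snps Character vector of eQTL SNPs after LD expansion
#'   ([expand_by_ld()]).
#' @param catalog Tibble `snp_id`, `trait` (and optionally `p_value`).
#' @param universe Universe size for enrichment; default the number of
#'   distinct catalog SNPs.
#' @return Tibble, one row per trait with at least one overlapping SNP:
#'   `trait`, `n_trait_snps`, `n_overlap`, `snps` (list column),
#'   `p_enrichment`.
#' @export
gwas_intersect <- function(expanded_snps, catalog, universe = NULL) {
  catalog <- as_tibble(catalog)
  if (!all(c("snp_id", "trait") %in% names(catalog))) {
    abort("catalog needs columns snp_id, trait")
  }
  bad <- is.na(catalog$snp_id) | is.na(catalog$trait) |
    catalog$snp_id == "" | catalog$trait == ""
  if (any(bad)) {
    warn(sprintf("skipping %d malformed catalog row(s)", sum(bad)))
    catalog <- catalog[!bad, ]
  }
  if (length(expanded_snps) == 0 || nrow(catalog) == 0) {
    return(tibble(trait = character(), n_trait_snps = integer(),
                  n_overlap = integer(), snps = list(),
                  p_enrichment = numeric()))
  }
  universe <- universe %||% dplyr::n_distinct(catalog$snp_id)
  set_b <- length(intersect(expanded_snps, unique(catalog$snp_id)))
  catalog |>
    distinct(.data$trait, .data$snp_id) |>
    group_by(.data$trait) |>
    summarise(
      n_trait_snps = dplyr::n(),
      n_overlap = sum(.data$snp_id %in% expanded_snps),
      snps = list(intersect(.data$snp_id, expanded_snps)),
      .groups = "drop"
    ) |>
    filter(.data$n_overlap > 0) |>
    mutate(p_enrichment = purrr::map2_dbl(
      .data$n_overlap, .data$n_trait_snps,
      function(k, K) hypergeom_enrichment(k, K, set_b, universe)
    ))
}

#' Map gene symbols through a homolog table
#'
#' Joins query symbols against a two-column homolog mapping (for example
#' mouse symbol to human symbol); symbols without a mapping are returned
#' separately. Conflicting duplicate mappings (one source symbol mapped to
#' several targets) are an error naming the symbol.
#'
#' @param gene_symbols Character vector of query symbols.
#' @param homolog_table Data frame whose first two columns are source and
#'   target symbols.
#' @return List with `mapped` (tibble `input`, `mapped`) and `unmapped`
#'   (character vector).
#' @export
map_homologs <- function(gene_symbols, homolog_table) {
  tab <- as_tibble(homolog_table)
  if (ncol(tab) < 2) abort("homolog_table needs two columns (source, target)")
  tab <- tab |> select(1:2) |> rlang::set_names(c("input", "mapped")) |>
    distinct()
  conflict <- tab |> count(.data$input) |> filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(sprintf("conflicting homolog mappings for: %s",
                  paste(utils::head(conflict$input, 5), collapse = ", ")))
  }
  mapped <- tibble(input = unique(gene_symbols)) |>
    inner_join(tab, by = "input")
  list(mapped = mapped,
       unmapped = setdiff(unique(gene_symbols), mapped$input))
}
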