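#' Enumerate cis SNP-probe pairs
#'
#' Pairs every probe with the SNPs on the same chromosome whose position
#' lies within `window` bp of the probe midpoint (inclusive at the
#' boundary). Probes with no cis SNP yield no pairs and therefore no
#' permutation threshold downstream.
#'
#' @param snp_annotation Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param probe_annotation Tibble with `probe_id`, `chrom`, `midpoint`
#'   (1-based).
#' @param window Cis window half-width in bp. Default 250000.
#' @return Tibble `probe_id`, `snp_id`, `distance` (signed,
#'   `pos - midpoint`).
#' @export
cis_pairs <- function(snp_annotation, probe_annotation, window = 250000) {
  as_tibble(probe_annotation) |>
    select("probe_id", "chrom", "midpoint") |>
    inner_join(as_tibble(snp_annotation) |> select("snp_id", "chrom", "pos"),
               by = "chrom", relationship = "many-to-many") |>
    mutate(distance = .data$pos - .data$midpoint) |>
    filter(abs(.data$distance) <= window) |>
    select("probe_id", "snp_id", "distance")
}

# Per-SNP OLS association of expression on allele count, with pairwise
# deletion of missing genotypes. G: n x m genotype matrix (NA = missing),
# y: length-n expression vector. Returns one row per usable SNP.
assoc_stats <- function(G, y) {
  m <- ncol(G)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(y)
    gg <- g[ok]; yy <- y[ok]
    n_used <- length(gg)
    if (n_used < 3 || length(unique(gg)) < 2) {
      out[[j]] <- NULL
      next
    }
    gc <- gg - mean(gg); yc <- yy - mean(yy)
    sxx <- sum(gc^2); syy <- sum(yc^2); sxy <- sum(gc * yc)
    beta <- sxy / sxx
    r2 <- if (syy == 0) 0 else sxy^2 / (sxx * syy)
    df <- n_used - 2
    tt <- sqrt(df) * sqrt(r2 / max(1 - r2, .Machine$double.eps))
    logp <- stats::pt(tt, df, lower.tail = FALSE, log.p = TRUE) + log(2)
    out[[j]] <- tibble(
      snp_id = colnames(G)[j], n_used = n_used, beta = beta, r2 = r2,
      p_nominal = min(1, 2 * stats::pt(tt, df, lower.tail = FALSE)),
      log10_p = pmin(0, logp / log(10))
    )
  }
  dropped <- colnames(G)[vapply(out, is.null, TRUE)]
  res <- bind_rows(out)
  attr(res, "dropped") <- dropped
  res
}

#' Additive linear-model association for one SNP-probe pair
#'
#' Ordinary least squares of expression on allele count (intercept plus
#' slope). Samples with a missing genotype are excluded pairwise. The
#' nominal p-value is the two-sided t-test on the slope with `n_used - 2`
#' degrees of freedom; `r2` is the squared Pearson correlation on the used
#' samples (the variance explained under the additive model). `log10_p` is
#' computed in log space and stays finite when `p_nominal` underflows.
#'
#' @param genotype Numeric vector of allele counts 0/1/2 with `NA` for
#'   missing.
#' @param expression Numeric vector, same length.
#' @return One-row tibble `n_used`, `beta`, `r2`, `p_nominal`, `log10_p`.
#' @export
#' @examples
#' linreg_assoc(c(0, 1, 2, 0, 1, 2), c(1.0, 2.0, 3.1, 0.9, 2.2, 2.8))
linreg_assoc <- function(genotype, expression) {
  if (length(genotype) != length(expression)) {
    abort("genotype and expression must have equal length")
  }
  res <- assoc_stats(matrix(genotype, ncol = 1,
                            dimnames = list(NULL, "snp")), expression)
  if (nrow(res) == 0) {
    abort(paste("association undefined: fewer than 3 samples or constant",
                "genotype after missing-data exclusion"))
  }
  res |> select(-"snp_id")
}

# Minimum nominal p across cis SNPs for n_perm phenotype permutations.
# One shared permutation of y per iteration is applied to every SNP of the
# probe (label swapping preserves the LD among the SNPs); missing genotypes
# are then excluded pairwise per SNP, mirroring the unpermuted analysis.
perm_min_p <- function(G, y, n_perm, seed) {
  n <- length(y)
  perm <- withr::with_seed(seed, {
    matrix(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)),
           n, n_perm)
  })
  Y <- matrix(y[perm], n, n_perm)
  minp <- rep(Inf, n_perm)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    ok <- !is.na(g)
    gg <- g[ok]
    if (sum(ok) < 3 || length(unique(gg)) < 2) next
    gc <- gg - mean(gg)
    Yc <- Y[ok, , drop = FALSE]
    Yc <- sweep(Yc, 2, colMeans(Yc))
    r2 <- colSums(gc * Yc)^2 /
      pmax(sum(gc^2) * colSums(Yc^2), .Machine$double.xmin)
    df <- sum(ok) - 2
    tt <- sqrt(df) * sqrt(r2 / pmax(1 - r2, .Machine$double.eps))
    p <- pmin(1, 2 * stats::pt(tt, df, lower.tail = FALSE))
    minp <- pmin(minp, p)
  }
  if (all(is.infinite(minp))) abort("no usable cis SNP for permutation")
  minp
}

#' Per-probe permutation significance threshold
#'
#' Implements phenotype-permutation (label-swapping) calibration: for each
#' of `n_perm` permutations the expression vector is shuffled once and
#' tested against every cis SNP of the probe; the minimum nominal p-value
#' across SNPs is recorded. The significance threshold is the `alpha` tail
#' of these minima, taken as the k-th smallest minimum with
#' `k = ceiling(alpha * n_perm)` (the 10th smallest of 10,000 at the default
#' `alpha = 0.001`), without interpolation.
#'
#' @param expression Numeric expression vector for the probe.
#' @param cis_genotypes Matrix samples x cis SNPs (allele counts, `NA`
#'   missing).
#' @param n_perm Number of permutations. Default 10000.
#' @param alpha Tail fraction of the min-p distribution. Default 0.001.
#' @param seed Integer seed; identical seeds give identical thresholds.
#' @return List of class `probe_threshold`: `p_threshold`, `min_p` (the
#'   `n_perm` permutation minima), `n_perm`, `alpha`.
#' @export
permute_probe <- function(expression, cis_genotypes, n_perm = 10000,
                          alpha = 0.001, seed = 1L) {
  assert_count(n_perm, "n_perm")
  assert_fraction(alpha, "alpha", lo_open = TRUE)
  if (is.null(dim(cis_genotypes))) {
    cis_genotypes <- matrix(cis_genotypes, ncol = 1)
  }
  if (ncol(cis_genotypes) == 0) abort("probe has no cis SNPs")
  minp <- perm_min_p(cis_genotypes, expression, n_perm, as.integer(seed))
  k <- ceiling(alpha * n_perm)
  structure(list(p_threshold = sort(minp)[k], min_p = minp,
                 n_perm = n_perm, alpha = alpha),
            class = "probe_threshold")
}

#' Map cis eQTLs genome-wide with permutation significance
#'
#' The full association engine: enumerates cis SNP-probe pairs within the
#' window, fits the additive linear model per pair with pairwise exclusion
#' of missing genotypes, computes a per-probe permutation threshold
#' ([permute_probe()]) using a deterministic per-probe random stream derived
#' from `seed`, and calls a pair significant when its nominal p-value is
#' strictly below its probe's threshold. Each probe is analysed
#' independently.
#'
#' @param genotypes A [genotype_panel()].
#' @param expression An [expression_panel()] (log2 scale recommended).
#' @param window Cis window half-width in bp. Default 250000.
#' @param n_perm Permutations per probe. Default 10000.
#' @param alpha Tail fraction for the threshold. Default 0.001.
#' @param seed Integer seed for all permutation streams.
#' @return An `eqtl_result` object; see [tidy.eqtl_result()] and
#'   [glance.eqtl_result()].
#' @export
map_cis_eqtl <- function(genotypes, expression, window = 250000,
                         n_perm = 10000, alpha = 0.001, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_panel"),
            inherits(expression, "expression_panel"))
  if (expression$state == "raw") {
    warn("expression panel is in raw state; association assumes log2 scale")
  }
  if (!identical(rownames(genotypes$genotypes), rownames(expression$values))) {
    abort("genotype and expression panels must share sample ids in order")
  }
  pairs <- cis_pairs(genotypes$snps, expression$probes, window)
  probes <- unique(pairs$probe_id)
  assoc_list <- vector("list", length(probes))
  thr_list <- vector("list", length(probes))
  dropped <- character()
  for (i in seq_along(probes)) {
    pid <- probes[i]
    snp_ids <- pairs$snp_id[pairs$probe_id == pid]
    G <- genotypes$genotypes[, snp_ids, drop = FALSE]
    y <- expression$values[, pid]
    a <- assoc_stats(G, y)
    dropped <- c(dropped, attr(a, "dropped"))
    if (nrow(a) == 0) next
    thr <- permute_probe(y, G, n_perm = n_perm, alpha = alpha,
                         seed = derive_seed(seed, pid))
    assoc_list[[i]] <- a |> mutate(probe_id = pid, .before = 1)
    thr_list[[i]] <- tibble(probe_id = pid, n_cis_snps = nrow(a),
                            n_perm = n_perm, alpha = alpha,
                            p_threshold = thr$p_threshold)
  }
  if (length(dropped)) {
    warn(sprintf("%d pair(s) skipped (constant genotype or too few calls)",
                 length(dropped)))
  }
  assoc <- bind_rows(assoc_list)
  thresholds <- bind_rows(thr_list)
  res <- call_eqtls(assoc, thresholds)
  res$assoc <- res$assoc |>
    left_join(pairs, by = c("probe_id", "snp_id")) |>
    left_join(genotypes$snps |> select("snp_id", "chrom", "pos"),
              by = "snp_id") |>
    left_join(expression$probes |>
                select(dplyr::all_of(c("probe_id",
                                       intersect("gene_symbol",
                                                 names(expression$probes))))),
              by = "probe_id") |>
    relocate("probe_id", "snp_id", "chrom", "pos", "distance")
  res$params <- list(window = window, n_perm = n_perm, alpha = alpha,
                     seed = seed)
  res$skipped_pairs <- dropped
  res
}

#' Call significant eQTL pairs against per-probe thresholds
#'
#' A pair is significant when its nominal p-value is strictly lower than
#' the permutation threshold of its own probe.
#'
#' @param assocs Tibble of association records with `probe_id`, `snp_id`,
#'   `p_nominal` (as produced by [linreg_assoc()] rows).
#' @param thresholds Tibble with `probe_id`, `p_threshold` (and typically
#'   `n_perm`, `alpha`).
#' @return An `eqtl_result` object: list with `assoc` (records plus
#'   `p_threshold`, `significant`) and `thresholds`.
#' @export
call_eqtls <- function(assocs, thresholds) {
  missing_thr <- setdiff(assocs$probe_id, thresholds$probe_id)
  if (length(missing_thr)) {
    abort(sprintf("no permutation threshold for probe(s): %s",
                  paste(utils::head(missing_thr, 5), collapse = ", ")))
  }
  assoc <- assocs |>
    left_join(thresholds |> select("probe_id", "p_threshold"),
              by = "probe_id") |>
    mutate(significant = .data$p_nominal < .data$p_threshold)
  structure(list(assoc = assoc, thresholds = thresholds),
            class = "eqtl_result")
}

#' @export
print.eqtl_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<eqtl_result> %d pairs tested across %d probes; ",
                     "%d significant pairs on %d probes\n"),
              g$n_pairs_tested, g$n_probes_tested, g$n_significant_pairs,
              g$n_significant_probes))
  invisible(x)
}

#' Tidy an eQTL result into its per-pair association table
#'
#' @param x An `eqtl_result`.
#' @param ... Unused.
#' @return Tibble with one row per tested SNP-probe pair: coordinates,
#'   `n_used`, `beta`, `r2`, `p_nominal`, `log10_p`, `p_threshold`,
#'   `significant`.
#' @export
tidy.eqtl_result <- function(x, ...) as_tibble(x$assoc)

#' One-row summary of an eQTL result
#'
#' @param x An `eqtl_result`.
#' @param ... Unused.
#' @return One-row tibble: pairs and probes tested, significant pair count,
#'   distinct significant probes, and distinct significant gene symbols
#'   (`NA` when the annotation carries no `gene_symbol`).
#' @export
glance.eqtl_result <- function(x, ...) {
  a <- x$assoc
  sig <- a |> filter(.data$significant)
  tibble(
    n_pairs_tested = nrow(a),
    n_probes_tested = dplyr::n_distinct(a$probe_id),
    n_significant_pairs = nrow(sig),
    n_significant_probes = dplyr::n_distinct(sig$probe_id),
    n_significant_genes = if ("gene_symbol" %in% names(sig)) {
      dplyr::n_distinct(sig$gene_symbol)
    } else NA_integer_
  )
}

#' Manhattan-style plot of an eQTL result
#'
#' @param object An `eqtl_result` whose association table carries `chrom`
#'   and `pos`.
#' @param ... Unused.
#' @return A ggplot: -log10 nominal p by position, faceted by chromosome,
#'   significant pairs highlighted.
#' @export
autoplot.eqtl_result <- function(object, ...) {
  a <- object$assoc
  stopifnot(all(c("chrom", "pos") %in% names(a)))
  ggplot2::ggplot(a, ggplot2::aes(x = .data$pos, y = -.data$log10_p,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)",
                  y = expression(-log[10] ~ italic(P)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}
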