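#' Delta-Ct from qPCR cycle thresholds
#'
#' `dCt = Ct(gene of interest) - Ct(endogenous control)` per record.
#' Negative values are allowed (gene more abundant than the control).
#'
#' @param qpcr Tibble with columns `ct_goi` and `ct_endctl` (cycles).
#' @return The input with a `dct` column appended.
#' @export
delta_ct <- function(qpcr) {
  qpcr <- as_tibble(qpcr)
  if (!all(c("ct_goi", "ct_endctl") %in% names(qpcr))) {
    abort("qpcr needs columns ct_goi, ct_endctl")
  }
  qpcr |> mutate(dct = .data$ct_goi - .data$ct_endctl)
}

#' Convert delta-Ct to linear expression
#'
#' `2^(-dCt)`: one cycle difference doubles or halves linear expression.
#'
#' @param dct Numeric delta-Ct values (cycles).
#' @return Linear-scale expression ratios.
#' @export
linear_expression <- function(dct) 2^(-dct)

#' Fold change of treated versus mock-treated samples
#'
#' Pairs treated and mock records per sample and gene and computes
#' `2^(-dCt_treated) / 2^(-dCt_mock) = 2^(dCt_mock - dCt_treated)`.
#'
#' @param qpcr Tibble with columns `sample_id`, `gene`, `condition`
#'   (values `"mock"` and `"treated"`), `ct_goi`, `ct_endctl`, and
#'   optionally `genotype` (carried through).
#' @return Tibble with one row per sample and gene: `sample_id`,
#'   (`genotype`,) `gene`, `fold_change`.
#' @export
fold_change <- function(qpcr) {
  q <- delta_ct(qpcr)
  if (!all(c("sample_id", "gene", "condition") %in% names(q))) {
    abort("qpcr needs columns sample_id, gene, condition")
  }
  if (!all(q$condition %in% c("mock", "treated"))) {
    abort('condition must be "mock" or "treated"')
  }
  keys <- intersect(c("sample_id", "genotype", "gene"), names(q))
  wide <- q |>
    select(dplyr::all_of(c(keys, "condition", "dct"))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "dct")
  if (anyNA(wide$mock) || anyNA(wide$treated)) {
    abort("every sample/gene needs both a mock and a treated record")
  }
  wide |>
    mutate(fold_change = 2^(.data$mock - .data$treated)) |>
    select(dplyr::all_of(keys), "fold_change")
}

#' Compare stimulation responses between genotype groups
#'
#' Nonparametric genotype-stratified testing: two genotype groups are
#' compared with a two-sided Mann-Whitney U test (exact p-value when the
#' combined sample size is at most 20 and there are no ties, normal
#' approximation otherwise); three or more groups use the Kruskal-Wallis
#' rank-sum test (chi-square approximation with tie correction) followed by
#' Dunn's pairwise z-tests on the shared mid-ranks with multiplicity
#' adjustment.
#'
#' @param responses Tibble with the response values and a grouping column,
#'   e.g. the output of [fold_change()].
#' @param value Name of the response column. Default `"fold_change"`.
#' @param group Name of the grouping column. Default `"genotype"`.
#' @param adjust Multiplicity adjustment for Dunn's tests: any
#'   [stats::p.adjust()] method. Default `"bonferroni"`; use `"none"` for
#'   unadjusted z-tests.
#' @return List of class `genotype_comparison`: `test` (`"mann_whitney"` or
#'   `"kruskal_wallis"`), `statistic`, `p_value`, `group_sizes`, and for
#'   three or more groups `pairwise` (tibble of Dunn z-tests:
#'   `group_1`, `group_2`, `z`, `p_unadjusted`, `p_adjusted`).
#' @export
compare_genotypes <- function(responses, value = "fold_change",
                              group = "genotype", adjust = "bonferroni") {
  responses <- as_tibble(responses)
  if (!all(c(value, group) %in% names(responses))) {
    abort(sprintf("responses needs columns %s and %s", value, group))
  }
  x <- responses[[value]]
  g <- factor(responses[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes == 0)) {
    abort("need at least 2 non-empty genotype groups")
  }
  if (length(sizes) == 2) {
    lv <- levels(g)
    exact <- length(x) <= 20 && !any(duplicated(x))
    wt <- stats::wilcox.test(x[g == lv[1]], x[g == lv[2]],
                             exact = exact, correct = !exact)
    out <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, exact = exact,
                group_sizes = as.integer(sizes))
  } else {
    kw <- stats::kruskal.test(x, g)
    out <- list(test = "kruskal_wallis", statistic = unname(kw$statistic),
                p_value = kw$p.value, group_sizes = as.integer(sizes),
                pairwise = dunn_test(x, g, adjust = adjust))
  }
  names(out$group_sizes) <- names(sizes)
  structure(out, class = "genotype_comparison")
}

# Dunn's post-hoc z-tests on the joint mid-ranks with tie-corrected
# variance: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
# T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
dunn_test <- function(x, g, adjust = "bonferroni") {
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_rank[p[1]] - mean_rank[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble(group_1 = pairs[1, ], group_2 = pairs[2, ], z = unname(z),
         p_unadjusted = unname(p),
         p_adjusted = stats::p.adjust(p, method = adjust))
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("<genotype_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Tidy a genotype comparison
#'
#' @param x A `genotype_comparison`.
#' @param ... Unused.
#' @return Tibble: the omnibus test row, followed by Dunn pairwise rows when
#'   present.
#' @export
tidy.genotype_comparison <- function(x, ...) {
  omnibus <- tibble(comparison = "omnibus", test = x$test,
                    statistic = x$statistic, p_value = x$p_value)
  if (is.null(x$pairwise)) return(omnibus)
  bind_rows(omnibus,
            x$pairwise |>
              transmute(comparison = paste(.data$group_1, "vs",
                                           .data$group_2),
                        test = "dunn_z", statistic = .data$z,
                        p_value = .data$p_adjusted))
}

#' One-row summary of a genotype comparison
#'
#' @param x A `genotype_comparison`.
#' @param ... Unused.
#' @return One-row tibble: test, statistic, p-value, group count and total
#'   n.
#' @export
glance.genotype_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_groups = length(x$group_sizes), n_total = sum(x$group_sizes))
}

#' Dot plot of stimulation responses by genotype
#'
#' @param responses Tibble with a response and a grouping column.
#' @param value,group Column names, as in [compare_genotypes()].
#' @return A ggplot: per-genotype jittered points with the group median, on
#'   a log2 fold-change axis.
#' @export
plot_genotype_response <- function(responses, value = "fold_change",
                                   group = "genotype") {
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data[[group]], y = .data[[value]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.8, colour = "steelblue") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = group, y = paste(value, "(log2 axis)")) +
    ggplot2::theme_minimal()
}
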