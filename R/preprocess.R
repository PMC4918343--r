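AUTOSOMES <- as.character(1:22)

qc_report <- function(rule, removed, retained, input) {
  stopifnot(sum(removed) + retained == input)
  tibble(rule = rule, removed = removed) |>
    bind_rows(tibble(rule = "retained", removed = retained)) |>
    rename(count = "removed")
}

#' SNP quality-control filter
#'
#' Retains autosomal SNPs with call rate at or above `min_call_rate` and at
#' least two distinct observed genotype values. A SNP failing several rules
#' is counted once, under the first rule in the fixed order non-autosome,
#' call-rate, monomorphic, so report counts are deterministic. A call rate
#' of exactly `min_call_rate` is retained (only rates strictly below are
#' removed).
#'
#' @param panel A [genotype_panel()].
#' @param min_call_rate Minimum fraction of non-missing calls. Default 0.95.
#' @param autosomes Chromosome labels counted as autosomal. Default
#'   `"1"`..`"22"`.
#' @return List with `panel` (filtered [genotype_panel()]) and `report`
#'   (tibble of per-rule removal counts; removed + retained equals input).
#' @export
filter_snps <- function(panel, min_call_rate = 0.95, autosomes = AUTOSOMES) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$genotypes) == 0) abort("empty genotype panel")
  g <- panel$genotypes
  call_rate <- colMeans(!is.na(g))
  n_distinct_geno <- apply(g, 2, function(x) length(unique(x[!is.na(x)])))
  non_auto <- !(panel$snps$chrom %in% autosomes)
  low_call <- !non_auto & call_rate < min_call_rate
  mono <- !non_auto & !low_call & n_distinct_geno < 2
  keep <- !(non_auto | low_call | mono)
  report <- qc_report(
    c("non_autosome", "call_rate", "monomorphic"),
    c(sum(non_auto), sum(low_call), sum(mono)),
    sum(keep), ncol(g)
  )
  out <- genotype_panel(g[, keep, drop = FALSE],
                        panel$snps[keep, , drop = FALSE])
  list(panel = out, report = report)
}

#' Probe quality-control filter
#'
#' Retains autosomal probes and, when `drop_snp_in_probe` is set, drops
#' probes whose sequence contains a common SNP (minor allele frequency at
#' least 1% — carried as the annotation flag `has_common_snp`).
#'
#' @param panel An [expression_panel()].
#' @param autosomes Chromosome labels counted as autosomal.
#' @param drop_snp_in_probe Drop probes flagged `has_common_snp`. Default
#'   `TRUE`.
#' @return List with `panel` and `report`, as [filter_snps()].
#' @export
filter_probes <- function(panel, autosomes = AUTOSOMES,
                          drop_snp_in_probe = TRUE) {
  stopifnot(inherits(panel, "expression_panel"))
  if (ncol(panel$values) == 0) abort("empty expression panel")
  non_auto <- !(panel$probes$chrom %in% autosomes)
  has_snp <- panel$probes[["has_common_snp"]] %||% rep(FALSE, ncol(panel$values))
  snp_in_probe <- !non_auto & drop_snp_in_probe & has_snp
  keep <- !(non_auto | snp_in_probe)
  report <- qc_report(
    c("non_autosome", "snp_in_probe"),
    c(sum(non_auto), sum(snp_in_probe)),
    sum(keep), ncol(panel$values)
  )
  out <- expression_panel(panel$values[, keep, drop = FALSE],
                          panel$probes[keep, , drop = FALSE],
                          state = panel$state)
  list(panel = out, report = report)
}

#' Flag probes detected in too few samples
#'
#' Probes detected in fewer than `min_fraction` of samples are flagged but
#' never removed: selective loss of expression can itself be biologically
#' interesting, so downstream analysis keeps the probes and the flag travels
#' with the annotation.
#'
#' @param panel An [expression_panel()].
#' @param detection_calls Logical samples x probes matrix of detection
#'   calls (an external input; see [simulate_detection_calls()]).
#' @param min_fraction Detection fraction below which a probe is flagged.
#'   Default 0.05.
#' @return Tibble `probe_id`, `detected_fraction`, `low_detection`.
#' @export
flag_low_detection <- function(panel, detection_calls, min_fraction = 0.05) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!identical(dim(detection_calls), dim(panel$values))) {
    abort("detection_calls must match the panel's samples x probes shape")
  }
  frac <- colMeans(detection_calls)
  tibble(probe_id = panel$probes$probe_id,
         detected_fraction = frac,
         low_detection = frac < min_fraction)
}

#' Quantile normalization followed by log2 transform
#'
#' Standard across-sample quantile normalization (each sample's rank-k value
#' is replaced by the mean rank-k value over samples; ties receive the mean
#' of the reference values at their tied ranks), then log2. Background
#' subtraction is not applied.
#'
#' @param panel An [expression_panel()] in `"raw"` state with strictly
#'   positive intensities.
#' @return The panel in `"quantile_log2"` state; every sample then shares
#'   one sorted value vector.
#' @export
quantile_normalize_log2 <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  if (panel$state != "raw") abort("panel must be in raw state")
  if (any(panel$values <= 0)) abort("intensities must be strictly positive")
  # limma normalizes columns; our samples are rows
  norm <- t(limma::normalizeQuantiles(t(panel$values), ties = TRUE))
  dimnames(norm) <- dimnames(panel$values)
  expression_panel(log2(norm), panel$probes, state = "quantile_log2")
}

#' Detect duplicate samples by expression correlation
#'
#' Flags unordered sample pairs whose squared Pearson correlation across
#' probes exceeds `r2_threshold`; such pairs are treated as technical
#' duplicates of one donor.
#'
#' @param panel An [expression_panel()].
#' @param r2_threshold Squared-correlation threshold. Default 0.98.
#' @return Tibble `sample_1`, `sample_2`, `r2` (possibly zero rows).
#' @export
detect_duplicates <- function(panel, r2_threshold = 0.98) {
  stopifnot(inherits(panel, "expression_panel"))
  n <- nrow(panel$values)
  if (n < 2) abort("need at least 2 samples")
  r2 <- stats::cor(t(panel$values))^2
  idx <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
  tibble(sample_1 = rownames(panel$values)[idx[, 1]],
         sample_2 = rownames(panel$values)[idx[, 2]],
         r2 = r2[idx])
}
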