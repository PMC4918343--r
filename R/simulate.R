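#' Simulation configuration for synthetic genotype/expression panels
#'
#' Defines the study conditions emulated by the generator: cohort size,
#' SNP panel with block LD structure, minor-allele-frequency spectrum,
#' missing-call rate, and a table of additive cis effects with a target
#' variance explained per effect. The defaults mirror a purified-neutrophil
#' microarray eQTL cohort of 114 donors.
#'
#' Genotypes are generated from a latent Gaussian copula: within each LD
#' block, adjacent latent variables follow an AR(1) process with correlation
#' `ld_decay`, and each latent value is thresholded to allele counts at the
#' Hardy-Weinberg genotype frequencies of the SNP's minor allele frequency
#' (drawn uniformly within `maf_range`).
#'
#' @param n_samples Number of samples (donors). Default 114.
#' @param n_snps Number of SNPs on the panel.
#' @param n_probes Number of expression probes.
#' @param maf_range Length-2 vector, lower/upper minor allele frequency in
#'   (0, 0.5].
#' @param ld_block_size SNPs per LD block (consecutive SNPs).
#' @param ld_decay Latent correlation between adjacent SNPs within a block,
#'   in \[0, 1\]; between-SNP correlation decays as `ld_decay^distance`.
#' @param missing_rate Fraction of genotype calls missing completely at
#'   random, in \[0, 1).
#' @param effect_table Data frame with columns `probe_id`, `snp_id`,
#'   `target_variance_explained` describing the true cis effects. `NULL`
#'   builds a default table pairing the first `n_effects` probes with a SNP
#'   in their own LD block at `target_r2`.
#' @param n_effects Number of default effects when `effect_table` is `NULL`.
#' @param target_r2 Target variance explained for default effects, in
#'   \[0, 1).
#' @param noise_sd Residual standard deviation on the log2 expression scale.
#' @param seed Integer seed; identical configs give bit-identical output.
#'
#' @return A `sim_config` list, validated (every effect SNP lies within
#'   +/-250 kbp of its probe midpoint in the generated annotation).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 50, n_snps = 40, n_probes = 8, seed = 1)
#' gp <- simulate_genotypes(cfg)
#' sim <- simulate_expression(gp, cfg)
#' sim$truth
sim_config <- function(n_samples = 114, n_snps = 100, n_probes = 20,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_decay = 0.8, missing_rate = 0.01,
                       effect_table = NULL, n_effects = 5, target_r2 = 0.5,
                       noise_sd = 1, seed = 1L) {
  assert_count(n_samples, "n_samples", min = 2)
  assert_count(n_snps, "n_snps")
  assert_count(n_probes, "n_probes")
  assert_count(ld_block_size, "ld_block_size")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must be (low, high) within (0, 0.5] with low <= high")
  }
  assert_fraction(ld_decay, "ld_decay")
  assert_fraction(missing_rate, "missing_rate", hi_open = TRUE)
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  cfg <- structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_probes = as.integer(n_probes), maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
    missing_rate = missing_rate, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
  ann <- make_annotations(cfg)
  if (is.null(effect_table)) {
    effect_table <- default_effect_table(cfg, ann, n_effects, target_r2)
  } else {
    effect_table <- as_tibble(effect_table)
    need <- c("probe_id", "snp_id", "target_variance_explained")
    if (!all(need %in% names(effect_table))) {
      abort("`effect_table` needs probe_id, snp_id, target_variance_explained")
    }
  }
  if (any(effect_table$target_variance_explained >= 1) ||
      any(effect_table$target_variance_explained < 0)) {
    abort("target_variance_explained must lie in [0, 1)")
  }
  bad_probe <- setdiff(effect_table$probe_id, ann$probes$probe_id)
  bad_snp <- setdiff(effect_table$snp_id, ann$snps$snp_id)
  if (length(bad_probe) || length(bad_snp)) {
    abort(sprintf("effect_table references unknown ids: %s",
                  paste(c(bad_probe, bad_snp), collapse = ", ")))
  }
  eff <- effect_table |>
    left_join(ann$snps |> select("snp_id", snp_chrom = "chrom", "pos"),
              by = "snp_id") |>
    left_join(ann$probes |>
                select("probe_id", probe_chrom = "chrom", "midpoint"),
              by = "probe_id")
  if (any(eff$snp_chrom != eff$probe_chrom |
          abs(eff$pos - eff$midpoint) > 250000)) {
    abort("every effect SNP must lie within +/-250 kbp of its probe midpoint")
  }
  cfg$effect_table <- effect_table
  cfg
}

default_effect_table <- function(cfg, ann, n_effects, target_r2) {
  assert_fraction(target_r2, "target_r2", hi_open = TRUE)
  n_effects <- min(n_effects, cfg$n_probes)
  if (n_effects == 0) {
    return(tibble(probe_id = character(), snp_id = character(),
                  target_variance_explained = numeric()))
  }
  probes <- ann$probes$probe_id[seq_len(n_effects)]
  # pair each probe with the mid-block SNP of its own block
  block_of_probe <- (match(probes, ann$probes$probe_id) - 1) %%
    n_blocks(cfg) + 1
  snp <- map_dbl(block_of_probe, function(b) {
    idx <- which(snp_block_index(cfg) == b)
    idx[ceiling(length(idx) / 2)]
  })
  tibble(probe_id = probes, snp_id = ann$snps$snp_id[snp],
         target_variance_explained = target_r2)
}

n_blocks <- function(cfg) ceiling(cfg$n_snps / cfg$ld_block_size)

snp_block_index <- function(cfg) {
  (seq_len(cfg$n_snps) - 1) %/% cfg$ld_block_size + 1
}

#' Generate SNP and probe annotations for a simulation
#'
#' Lays out LD blocks of consecutive SNPs along autosomes (5 kbp spacing
#' within a block, 1 Mbp between block starts, so blocks are separated by
#' more than a cis window) and places each probe midpoint at the centre of
#' one block, guaranteeing at least one SNP within +/-250 kbp of every
#' probe. Coordinates are 1-based; chromosomes are autosomal labels.
#'
#' @param config A [sim_config()] (the effect table is not consulted).
#' @return List with tibbles `snps` (`snp_id`, `chrom`, `pos`, `ref`, `alt`)
#'   and `probes` (`probe_id`, `chrom`, `midpoint`, `gene_symbol`,
#'   `has_common_snp`).
#' @export
make_annotations <- function(config) {
  nb <- n_blocks(config)
  spacing <- 5000L
  span <- (config$ld_block_size - 1L) * spacing
  if (span > 500000L) {
    abort("ld_block_size too large: block span must stay within one cis window")
  }
  n_chrom <- min(22L, nb)
  block_chrom <- (seq_len(nb) - 1L) %% n_chrom + 1L
  block_rank <- stats::ave(seq_len(nb), block_chrom, FUN = seq_along)
  block_start <- (block_rank - 1L) * 1000000L + 1L
  blk <- snp_block_index(config)
  within <- stats::ave(seq_len(config$n_snps), blk, FUN = seq_along)
  snps <- tibble(
    snp_id = sprintf("rs%04d", seq_len(config$n_snps)),
    chrom = as.character(block_chrom[blk]),
    pos = block_start[blk] + (within - 1L) * spacing,
    ref = "A", alt = "G"
  )
  probe_block <- (seq_len(config$n_probes) - 1L) %% nb + 1L
  probe_rank <- stats::ave(seq_len(config$n_probes), probe_block,
                           FUN = seq_along)
  block_span <- map_dbl(seq_len(nb), function(b) {
    k <- sum(blk == b)
    (k - 1L) * spacing
  })
  probes <- tibble(
    probe_id = sprintf("probe_%04d", seq_len(config$n_probes)),
    chrom = as.character(block_chrom[probe_block]),
    midpoint = block_start[probe_block] +
      floor(block_span[probe_block] / 2) + (probe_rank - 1L) * 100L,
    gene_symbol = sprintf("GENE%04d", seq_len(config$n_probes)),
    has_common_snp = FALSE
  )
  list(snps = snps, probes = probes)
}

#' Simulate array-style genotypes with block LD and missing calls
#'
#' Draws a per-SNP minor allele frequency uniformly within
#' `config$maf_range`, generates latent AR(1) Gaussians within each LD block
#' (adjacent correlation `ld_decay`), and thresholds them at the
#' Hardy-Weinberg cutpoints to allele counts 0/1/2. Calls are then masked
#' missing completely at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()]. Bit-identical for identical configs.
#' @export
simulate_genotypes <- function(config) {
  ann <- make_annotations(config)
  n <- config$n_samples
  m <- config$n_snps
  blk <- snp_block_index(config)
  g <- withr::with_seed(config$seed, {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    z <- matrix(NA_real_, n, m)
    rho <- config$ld_decay
    for (j in seq_len(m)) {
      e <- stats::rnorm(n)
      z[, j] <- if (j > 1 && blk[j] == blk[j - 1]) {
        rho * z[, j - 1] + sqrt(1 - rho^2) * e
      } else e
    }
    u <- stats::pnorm(z)
    q <- 1 - maf
    g <- matrix(0, n, m)
    for (j in seq_len(m)) {
      g[, j] <- (u[, j] > q[j]^2) + (u[, j] > q[j]^2 + 2 * maf[j] * q[j])
    }
    if (config$missing_rate > 0) {
      g[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- NA
    }
    g
  })
  dimnames(g) <- list(sprintf("sample_%03d", seq_len(n)), ann$snps$snp_id)
  genotype_panel(g, ann$snps)
}

#' Simulate expression with additive cis effects of known variance explained
#'
#' Every probe receives Gaussian noise on the log2 scale around a baseline;
#' probes listed in the config's effect table additionally receive
#' `beta * genotype`, with `beta` scaled so that
#' `beta^2 Var(g) / (beta^2 Var(g) + noise_sd^2)` equals the requested
#' variance explained (using the empirical genotype variance of this draw).
#' Missing genotypes are mean-imputed for phenotype generation only.
#'
#' @param genotypes A [genotype_panel()] from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @param output `"log2"` returns values on the analysis (log2) scale;
#'   `"intensity"` returns raw intensities `2^y` (state `"raw"`), suitable
#'   for exercising normalization.
#' @param baseline Mean log2 expression level.
#' @return List with `expression` (an [expression_panel()]) and `truth`
#'   (tibble `probe_id`, `snp_id`, `true_beta`,
#'   `target_variance_explained`).
#' @export
simulate_expression <- function(genotypes, config,
                                output = c("log2", "intensity"),
                                baseline = 8) {
  output <- match.arg(output)
  eff <- config$effect_table
  if (length(setdiff(eff$snp_id, genotypes$snps$snp_id))) {
    abort("effect table references SNPs absent from the genotype panel")
  }
  ann <- make_annotations(config)
  if (length(setdiff(eff$probe_id, ann$probes$probe_id))) {
    abort("effect table references unknown probes")
  }
  n <- nrow(genotypes$genotypes)
  y <- withr::with_seed(derive_seed(config$seed, "expression"), {
    y <- baseline + matrix(stats::rnorm(n * config$n_probes,
                                        sd = config$noise_sd),
                           n, config$n_probes)
    truth_beta <- numeric(nrow(eff))
    for (i in seq_len(nrow(eff))) {
      g <- genotypes$genotypes[, eff$snp_id[i]]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      ve <- eff$target_variance_explained[i]
      sdg <- stats::sd(g)
      beta <- if (sdg == 0) {
        warn(sprintf("SNP %s is constant in this draw; effect dropped",
                     eff$snp_id[i]))
        0
      } else if (config$noise_sd == 0) {
        if (ve > 0) 1 else 0
      } else {
        config$noise_sd * sqrt(ve / (1 - ve)) / sdg
      }
      truth_beta[i] <- beta
      j <- match(eff$probe_id[i], ann$probes$probe_id)
      y[, j] <- y[, j] + beta * g
    }
    attr(y, "truth_beta") <- truth_beta
    y
  })
  truth <- tibble(probe_id = eff$probe_id, snp_id = eff$snp_id,
                  true_beta = attr(y, "truth_beta"),
                  target_variance_explained = eff$target_variance_explained)
  attr(y, "truth_beta") <- NULL
  dimnames(y) <- list(rownames(genotypes$genotypes), ann$probes$probe_id)
  panel <- if (output == "intensity") {
    expression_panel(2^y, ann$probes, state = "raw")
  } else {
    expression_panel(y, ann$probes, state = "log2")
  }
  list(expression = panel, truth = truth)
}

#' Build a GWAS-catalog-style fixture table
#'
#' Produces deterministic catalog records (`snp_id`, `trait`, `p_value`)
#' crossing the given SNPs with the given traits, as a stand-in for a
#' published-association catalog in tests and synthetic pipelines.
#'
#' @param snp_ids Character vector of SNP ids (non-empty).
#' @param traits Character vector of trait names.
#' @param seed Integer seed for the reported p-values.
#' @param fraction Fraction of the full SNP x trait cross to keep (sampled
#'   deterministically); 1 keeps every combination.
#' @return Tibble with one row per retained (SNP, trait) record.
#' @export
make_catalog_fixture <- function(snp_ids, traits, seed = 1L, fraction = 1) {
  if (length(snp_ids) == 0) abort("`snp_ids` must be non-empty")
  if (length(traits) == 0) abort("`traits` must be non-empty")
  assert_fraction(fraction, "fraction", lo_open = TRUE)
  full <- tidyr::expand_grid(snp_id = snp_ids, trait = traits)
  withr::with_seed(as.integer(seed), {
    if (fraction < 1) {
      keep <- sort(sample.int(nrow(full), ceiling(fraction * nrow(full))))
      full <- full[keep, ]
    }
    full$p_value <- 10^stats::runif(nrow(full), -12, -5)
  })
  full
}

#' Simulate per-sample detection calls for an expression panel
#'
#' The array platform's detection p-value machinery is out of scope; this
#' fabricates a logical samples x probes detection matrix with a given
#' per-call detection probability, optionally forcing some probes to low
#' detection.
#'
#' @param panel An [expression_panel()].
#' @param detect_prob Probability a call is detected.
#' @param low_probes Probe ids forced to `low_prob` detection.
#' @param low_prob Detection probability for `low_probes`.
#' @param seed Integer seed.
#' @return Logical matrix, samples x probes.
#' @export
simulate_detection_calls <- function(panel, detect_prob = 0.95,
                                     low_probes = character(),
                                     low_prob = 0.02, seed = 1L) {
  n <- nrow(panel$values); m <- ncol(panel$values)
  pr <- rep(detect_prob, m)
  pr[match(low_probes, colnames(panel$values))] <- low_prob
  withr::with_seed(as.integer(seed), {
    calls <- matrix(stats::runif(n * m), n, m) < rep(pr, each = n)
  })
  dimnames(calls) <- dimnames(panel$values)
  calls
}
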