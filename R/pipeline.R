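#' Configuration for a full synthetic pipeline run
#'
#' Gathers every stage threshold with its default (SNP call rate 0.95,
#' probe detection 0.05, duplicate r-squared 0.98, cis window 250,000 bp,
#' 10,000 permutations at the 0.001 tail, LD threshold 0.8) together with
#' the simulation settings and the run seed. A config is a plain list and
#' serializes to YAML, so a run is reproducible from the config file alone.
#'
#' @param sim A [sim_config()], or a list of arguments for one.
#' @param min_call_rate,min_detection,dup_r2,window,n_perm,alpha,ld_threshold
#'   Stage thresholds; see the stage functions for their meaning.
#' @param seed Integer seed governing every random stream of the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = list(), min_call_rate = 0.95,
                            min_detection = 0.05, dup_r2 = 0.98,
                            window = 250000, n_perm = 10000, alpha = 0.001,
                            ld_threshold = 0.8, seed = 1L) {
  assert_fraction(min_call_rate, "min_call_rate")
  assert_fraction(min_detection, "min_detection")
  assert_fraction(dup_r2, "dup_r2")
  assert_fraction(ld_threshold, "ld_threshold")
  assert_fraction(alpha, "alpha", lo_open = TRUE)
  assert_count(n_perm, "n_perm")
  assert_count(window, "window")
  if (!inherits(sim, "sim_config")) {
    sim$seed <- sim$seed %||% seed
    sim <- do.call(sim_config, sim)
  }
  structure(list(sim = sim, min_call_rate = min_call_rate,
                 min_detection = min_detection, dup_r2 = dup_r2,
                 window = window, n_perm = as.integer(n_perm), alpha = alpha,
                 ld_threshold = ld_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments, with `sim` holding [sim_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim$maf_range)) y$sim$maf_range <- unlist(y$sim$maf_range)
  do.call(pipeline_config, y)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate, preprocess, eQTL mapping, cross-dataset overlap
#' and GWAS-catalog intersection as one reproducible run: every stage
#' output is written under `out_dir`, per-stage record counts are asserted
#' (records in = records out + records removed) and collected in
#' `log.json`. Re-running with the same config reproduces identical
#' outputs.
#'
#' The overlap and GWAS stages are exercised against synthetic external
#' datasets derived deterministically from the run's own significant eQTLs
#' (a fraction of them re-labelled as the external studies, plus a catalog
#' fixture), so the whole surface runs without any download.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory for the run.
#' @return Invisibly, a list with the stage results (`genotypes`,
#'   `expression`, `qc`, `eqtl`, `overlap`, `gwas`, `log`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("neutroqtl")),
              stages = list())

  # --- simulate ---------------------------------------------------------
  gp <- simulate_genotypes(config$sim)
  sim <- simulate_expression(gp, config$sim, output = "intensity")
  calls <- simulate_detection_calls(sim$expression,
                                    seed = derive_seed(config$seed, "calls"))
  write_genotype_tsv(gp, file.path(out_dir, "simulate"))
  write_expression_tsv(sim$expression, file.path(out_dir, "simulate"))
  readr::write_tsv(sim$truth, file.path(out_dir, "simulate", "truth.tsv"))
  log$stages$simulate <- list(n_samples = nrow(gp$genotypes),
                              n_snps = ncol(gp$genotypes),
                              n_probes = ncol(sim$expression$values))

  # --- preprocess -------------------------------------------------------
  snp_qc <- filter_snps(gp, min_call_rate = config$min_call_rate)
  probe_qc <- filter_probes(sim$expression)
  flags <- flag_low_detection(probe_qc$panel,
                              calls[, probe_qc$panel$probes$probe_id,
                                    drop = FALSE],
                              min_fraction = config$min_detection)
  norm <- quantile_normalize_log2(probe_qc$panel)
  dups <- detect_duplicates(norm, r2_threshold = config$dup_r2)
  if (nrow(dups)) {
    keep <- setdiff(rownames(norm$values), unique(dups$sample_2))
    norm <- expression_panel(norm$values[keep, , drop = FALSE],
                             norm$probes, state = norm$state)
    snp_qc$panel <- genotype_panel(
      snp_qc$panel$genotypes[keep, , drop = FALSE], snp_qc$panel$snps)
  }
  qc <- bind_rows(snp_qc$report |> mutate(stage = "snp", .before = 1),
                  probe_qc$report |> mutate(stage = "probe", .before = 1))
  dir.create(file.path(out_dir, "preprocess"), showWarnings = FALSE)
  readr::write_tsv(qc, file.path(out_dir, "preprocess", "qc_report.tsv"))
  readr::write_tsv(flags, file.path(out_dir, "preprocess",
                                    "low_detection.tsv"))
  jsonlite::write_json(
    list(qc = qc, duplicates = dups,
         n_low_detection = sum(flags$low_detection)),
    file.path(out_dir, "preprocess", "qc_report.json"),
    auto_unbox = TRUE, digits = NA)
  stopifnot(sum(qc$count[qc$stage == "snp"]) == ncol(gp$genotypes),
            sum(qc$count[qc$stage == "probe"]) ==
              ncol(sim$expression$values))
  log$stages$preprocess <- list(
    snps_in = ncol(gp$genotypes),
    snps_retained = ncol(snp_qc$panel$genotypes),
    probes_in = ncol(sim$expression$values),
    probes_retained = ncol(norm$values),
    duplicates_removed = length(unique(dups$sample_2)),
    low_detection_flagged = sum(flags$low_detection))

  # --- map-eqtl ---------------------------------------------------------
  eqtl <- map_cis_eqtl(snp_qc$panel, norm, window = config$window,
                       n_perm = config$n_perm, alpha = config$alpha,
                       seed = config$seed)
  dir.create(file.path(out_dir, "eqtl"), showWarnings = FALSE)
  readr::write_tsv(tidy(eqtl), file.path(out_dir, "eqtl", "eqtl_table.tsv"))
  readr::write_tsv(eqtl$thresholds,
                   file.path(out_dir, "eqtl", "thresholds.tsv"))
  log$stages$map_eqtl <- as.list(glance(eqtl))

  # --- overlap + gwas ---------------------------------------------------
  sig <- tidy(eqtl) |> filter(.data$significant)
  ld <- ld_matrix(snp_qc$panel)
  dir.create(file.path(out_dir, "overlap"), showWarnings = FALSE)
  if (nrow(sig) > 0) {
    ours <- sig |> select("probe_id", "gene_symbol", "snp_id")
    probes <- unique(ours$probe_id)
    ext_b <- ours |> filter(.data$probe_id %in%
                              probes[seq_len(ceiling(length(probes) / 2))])
    ext_c <- ours |> filter(.data$probe_id %in%
                              probes[seq_len(ceiling(length(probes) / 4))])
    rep <- share_across_datasets(ours,
                                 ext_b |> select("gene_symbol", "snp_id"),
                                 ext_c |> select("gene_symbol", "snp_id"),
                                 ld = ld, threshold = config$ld_threshold)
    readr::write_tsv(tidy(rep),
                     file.path(out_dir, "overlap", "overlap_report.tsv"))
    jsonlite::write_json(as.list(glance(rep)),
                         file.path(out_dir, "overlap",
                                   "overlap_report.json"),
                         auto_unbox = TRUE, digits = NA)
    expanded <- expand_by_ld(unique(sig$snp_id), ld,
                             threshold = config$ld_threshold)
    catalog <- make_catalog_fixture(
      colnames(ld), paste0("trait_", 1:3),
      seed = derive_seed(config$seed, "catalog"), fraction = 0.3)
    gwas <- gwas_intersect(expanded, catalog)
    readr::write_tsv(gwas |> select(-"snps"),
                     file.path(out_dir, "overlap", "gwas_overlap.tsv"))
    log$stages$overlap <- list(total = rep$total,
                               n_expanded_snps = length(expanded),
                               n_gwas_traits = nrow(gwas))
  } else {
    rep <- NULL; gwas <- NULL
    log$stages$overlap <- list(total = 0, n_expanded_snps = 0,
                               n_gwas_traits = 0)
  }

  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genotypes = snp_qc$panel, expression = norm, qc = qc,
                 eqtl = eqtl, overlap = rep, gwas = gwas, log = log))
}
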