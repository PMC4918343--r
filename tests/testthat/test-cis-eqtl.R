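test_that("cis pairing is inclusive at exactly 250 kbp and chromosome-aware", {
  probes <- data.frame(probe_id = "p1", chrom = "1", midpoint = 1e6)
  snps <- data.frame(
    snp_id = c("at_mid", "at_edge", "past_edge", "other_chrom"),
    chrom = c("1", "1", "1", "2"),
    pos = c(1e6, 1e6 + 250000, 1e6 + 250001, 1e6))
  pairs <- cis_pairs(snps, probes)
  expect_setequal(pairs$snp_id, c("at_mid", "at_edge"))
  expect_equal(pairs$distance[pairs$snp_id == "at_mid"], 0)
  # a probe with no cis SNP yields no pairs
  far <- data.frame(snp_id = "rsf", chrom = "1", pos = 9e6)
  expect_equal(nrow(cis_pairs(far, probes)), 0)
})

test_that("linreg_assoc matches the closed-form OLS oracle", {
  # worked example, frozen from the closed form: slope Sxy/Sxx = 4/4
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(1.0, 2.0, 3.1, 0.9, 2.2, 2.8)
  fit <- linreg_assoc(g, y)
  orc <- ols_oracle(g, y)
  expect_equal(fit$beta, 1.0)
  expect_equal(fit$r2, 16 / (4 * 4.1))
  expect_equal(fit$p_nominal, orc$p, tolerance = 1e-12)

  # perfect fit
  fit1 <- linreg_assoc(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))
  expect_equal(fit1$r2, 1)
  expect_equal(fit1$beta, 1)

  # random instances against the oracle
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    g <- hw_genotypes(n, stats::runif(1, 0.15, 0.5))
    if (length(unique(g)) < 2) next
    y <- stats::rnorm(n) + stats::runif(1, -1, 1) * g
    fit <- linreg_assoc(g, y)
    orc <- ols_oracle(g, y)
    expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
    expect_equal(fit$r2, orc$r2, tolerance = 1e-10)
    expect_equal(fit$p_nominal, orc$p, tolerance = 1e-10)
  }
})

test_that("missing genotypes are excluded pairwise", {
  g <- c(0, 1, 2, 0, 1, 2, NA)
  y <- c(1.0, 2.0, 3.1, 0.9, 2.2, 2.8, 50)
  fit <- linreg_assoc(g, y)
  expect_equal(fit$n_used, 6)
  expect_equal(fit$beta, linreg_assoc(g[1:6], y[1:6])$beta)
  # degenerate inputs are an error
  expect_error(linreg_assoc(c(1, 1, 1, 1), stats::rnorm(4)), "undefined")
  expect_error(linreg_assoc(c(0, 1, NA, NA), stats::rnorm(4)), "undefined")
})

test_that("permutation thresholds are calibrated, deterministic, and
           LD-insensitive", {
  set.seed(23)
  g <- hw_genotypes(200, 0.3)
  y <- stats::rnorm(200)
  thr <- permute_probe(y, g, n_perm = 1000, alpha = 0.05, seed = 99)
  # with one cis SNP the null min-p is uniform, so the 5% tail sits near 0.05
  expect_lt(abs(thr$p_threshold - 0.05), 0.025)
  # determinism
  thr2 <- permute_probe(y, g, n_perm = 1000, alpha = 0.05, seed = 99)
  expect_identical(thr$min_p, thr2$min_p)
  # alpha = 1 returns the largest permutation minimum
  thr_max <- permute_probe(y, g, n_perm = 200, alpha = 1, seed = 5)
  expect_equal(thr_max$p_threshold, max(thr_max$min_p))
  # a perfectly correlated second SNP adds no multiplicity
  G2 <- cbind(a = g, b = g)
  thr_dup <- permute_probe(y, G2, n_perm = 500, alpha = 0.05, seed = 7)
  thr_one <- permute_probe(y, matrix(g, ncol = 1, dimnames = list(NULL, "a")),
                           n_perm = 500, alpha = 0.05, seed = 7)
  expect_identical(thr_dup$min_p, thr_one$min_p)
  expect_error(permute_probe(y, matrix(numeric(0), 200, 0)), "no cis SNP")
})

test_that("eQTL calling is strict at the threshold and joins by probe", {
  assocs <- tibble::tibble(probe_id = c("p1", "p1", "p2"),
                           snp_id = c("a", "b", "c"),
                           p_nominal = c(0.001, 0.0005, 1))
  thr <- tibble::tibble(probe_id = c("p1", "p2"),
                        p_threshold = c(0.001, 0.05))
  res <- call_eqtls(assocs, thr)
  # p equal to the threshold is NOT significant
  expect_equal(res$assoc$significant, c(FALSE, TRUE, FALSE))
  expect_error(call_eqtls(assocs |>
                            dplyr::mutate(probe_id = c("p1", "p1", "p9")),
                          thr), "p9")
  # all p = 1 yields nothing
  res1 <- call_eqtls(assocs |> dplyr::mutate(p_nominal = 1), thr)
  expect_equal(sum(res1$assoc$significant), 0)
})

test_that("true effects are recovered and the result surfaces are tidy", {
  cfg <- sim_config(n_samples = 114, n_snps = 50, n_probes = 10,
                    ld_block_size = 5, n_effects = 5, target_r2 = 0.5,
                    missing_rate = 0.02, seed = 101)
  gp <- simulate_genotypes(cfg)
  sim <- simulate_expression(gp, cfg)
  res <- map_cis_eqtl(gp, sim$expression, n_perm = 1000, alpha = 0.001,
                      seed = 101)
  tab <- tidy(res)
  sig_probes <- unique(tab$probe_id[tab$significant])
  expect_true(all(sim$truth$probe_id %in% sig_probes))
  # at most one of the 5 null probes slips through at the 0.001 tail
  expect_lte(length(setdiff(sig_probes, sim$truth$probe_id)), 1)
  g <- glance(res)
  expect_equal(g$n_probes_tested, 10)
  expect_equal(g$n_significant_probes, length(sig_probes))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_true(all(tab$p_nominal > 0 & tab$p_nominal <= 1))
  expect_true(all(tab$n_used <= 114))
  # monotonicity: the true pair has far smaller p than its probe's others
  p <- ggplot2::ggplot_build(autoplot(res))
  expect_gt(length(p$data), 0)
})

test_that("stronger simulated effects never weaken the association", {
  cfg_lo <- sim_config(n_samples = 114, n_snps = 10, n_probes = 1,
                       n_effects = 1, target_r2 = 0.2, missing_rate = 0,
                       seed = 55)
  cfg_hi <- sim_config(n_samples = 114, n_snps = 10, n_probes = 1,
                       n_effects = 1, target_r2 = 0.7, missing_rate = 0,
                       seed = 55)
  gp <- simulate_genotypes(cfg_lo)   # identical genotypes for both configs
  lo <- simulate_expression(gp, cfg_lo)
  hi <- simulate_expression(gp, cfg_hi)
  p_lo <- linreg_assoc(gp$genotypes[, lo$truth$snp_id],
                       lo$expression$values[, lo$truth$probe_id])$p_nominal
  p_hi <- linreg_assoc(gp$genotypes[, hi$truth$snp_id],
                       hi$expression$values[, hi$truth$probe_id])$p_nominal
  expect_lt(p_hi, p_lo)
})
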