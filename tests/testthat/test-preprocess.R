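make_geno <- function(g, chrom = rep("1", ncol(g))) {
  colnames(g) <- paste0("rs", seq_len(ncol(g)))
  rownames(g) <- paste0("s", seq_len(nrow(g)))
  genotype_panel(g, data.frame(snp_id = colnames(g), chrom = chrom,
                               pos = seq_len(ncol(g)) * 1000))
}

make_expr <- function(v, chrom = rep("1", ncol(v)), has_snp = NULL,
                      state = "raw") {
  colnames(v) <- paste0("p", seq_len(ncol(v)))
  rownames(v) <- paste0("s", seq_len(nrow(v)))
  expression_panel(v, data.frame(
    probe_id = colnames(v), chrom = chrom, midpoint = seq_len(ncol(v)) * 1e4,
    has_common_snp = has_snp %||% rep(FALSE, ncol(v))), state = state)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SNP filter applies the call-rate boundary at 95% of 114", {
  n <- 114
  g <- matrix(rep(0:2, length.out = n * 3), n, 3)
  g[1:6, 1] <- NA                 # 108/114 = 94.7% -> removed
  g[1:5, 2] <- NA                 # 109/114 = 95.6% -> retained
  panel <- make_geno(g)
  res <- filter_snps(panel)
  expect_false("rs1" %in% res$panel$snps$snp_id)
  expect_true(all(c("rs2", "rs3") %in% res$panel$snps$snp_id))
})

test_that("SNP filter removes monomorphic and non-autosomal SNPs once each", {
  g <- matrix(rep(0:2, length.out = 60), 20, 3)
  g[, 2] <- 2                          # monomorphic
  g[1:2, 3] <- NA
  panel <- make_geno(g, chrom = c("1", "1", "X"))
  res <- filter_snps(panel)
  expect_equal(res$panel$snps$snp_id, "rs1")
  counts <- setNames(res$report$count, res$report$rule)
  # rs3 is on X and counted under the first rule only
  expect_equal(counts[["non_autosome"]], 1)
  expect_equal(counts[["monomorphic"]], 1)
  expect_equal(counts[["call_rate"]], 0)
  expect_equal(sum(res$report$count), 3)   # conservation
  # idempotence
  res2 <- filter_snps(res$panel)
  expect_identical(res2$panel$genotypes, res$panel$genotypes)
})

test_that("probe filter drops non-autosomal and SNP-in-probe probes", {
  v <- matrix(stats::runif(10 * 10, 1, 10), 10, 10)
  panel <- make_expr(v, chrom = c(rep("X", 3), rep("2", 7)),
                     has_snp = c(rep(FALSE, 3), TRUE, TRUE, rep(FALSE, 5)))
  res <- filter_probes(panel)
  expect_equal(ncol(res$panel$values), 5)
  expect_equal(sum(res$report$count), 10)
  # flag unset retains SNP-in-probe probes
  res_keep <- filter_probes(panel, drop_snp_in_probe = FALSE)
  expect_equal(ncol(res_keep$panel$values), 7)
  # identity on an already-clean panel
  clean <- make_expr(v)
  expect_identical(filter_probes(clean)$panel$values, clean$values)
})

test_that("low-detection flagging uses the 5%-of-samples boundary", {
  n <- 114
  v <- matrix(stats::runif(n * 3, 1, 10), n, 3)
  panel <- make_expr(v)
  calls <- matrix(FALSE, n, 3, dimnames = dimnames(v))
  calls[1:5, 2] <- TRUE             # 5/114 = 4.39% -> flagged
  calls[1:6, 3] <- TRUE             # 6/114 = 5.26% -> not flagged
  flags <- flag_low_detection(panel, calls)
  expect_equal(flags$low_detection, c(TRUE, TRUE, FALSE))
  expect_true(all(!flag_low_detection(panel, calls,
                                      min_fraction = 0)$low_detection))
  expect_error(flag_low_detection(panel, calls[1:10, ]), "shape|match")
})

test_that("quantile normalization matches the 2-sample worked example", {
  v <- rbind(s1 = c(1, 3), s2 = c(2, 4))
  panel <- make_expr(v)
  out <- quantile_normalize_log2(panel)
  expect_equal(unname(out$values),
               rbind(c(log2(1.5), log2(3.5)), c(log2(1.5), log2(3.5))))
  expect_equal(out$state, "quantile_log2")
})

test_that("quantile normalization equalizes sample distributions", {
  set.seed(31)
  v <- matrix(stats::rlnorm(20 * 50, 3, 1), 20, 50)
  panel <- make_expr(v)
  out <- quantile_normalize_log2(panel)
  sorted <- apply(out$values, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # identical samples: normalization reduces to the log2 transform
  same <- matrix(rep(stats::runif(30, 1, 10), each = 4), 4, 30)
  expect_equal(unname(quantile_normalize_log2(make_expr(same))$values),
               unname(log2(same)))
  # guards
  expect_error(quantile_normalize_log2(out), "raw")
  bad <- make_expr(matrix(c(-1, 2, 3, 4), 2, 2))
  expect_error(quantile_normalize_log2(bad), "positive")
})

test_that("duplicate detection finds exact copies and spares noise", {
  set.seed(7)
  v <- matrix(stats::rnorm(6 * 1000), 6, 1000)
  v[2, ] <- v[1, ]                       # exact duplicate pair
  panel <- make_expr(v)
  dup <- detect_duplicates(panel)
  expect_equal(nrow(dup), 1)
  expect_equal(sort(c(dup$sample_1, dup$sample_2)), c("s1", "s2"))
  expect_equal(dup$r2, 1)
  # independent noise panels report nothing
  v2 <- matrix(stats::rnorm(6 * 1000), 6, 1000)
  expect_equal(nrow(detect_duplicates(make_expr(v2))), 0)
  # threshold 1.0 reports only numerically perfect pairs
  expect_equal(nrow(detect_duplicates(panel, r2_threshold = 1.0)), 0)
  expect_error(detect_duplicates(make_expr(v[1, , drop = FALSE])), "2 samples")
})
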