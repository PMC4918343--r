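test_that("genotypic r2 matches the direct correlation and is
           flip-invariant", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  g2 <- c(0, 1, 1, 2, 2, 2)
  expect_equal(ld_r2(g1, g2), 27 / 40)   # (Sxy)^2 / (Sxx Syy) = 9 / (4*10/3)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1))
  expect_equal(ld_r2(2 - g1, g2), ld_r2(g1, g2))
  expect_true(is.na(ld_r2(g1, rep(1, 6))))
  expect_error(ld_r2(c(0, NA, NA, NA, 1, 2), c(0, 1, 2, 0, NA, NA)),
               "pairwise-complete")
})

test_that("LD matrix is symmetric with unit diagonal in [0,1]", {
  cfg <- sim_config(n_samples = 120, n_snps = 20, missing_rate = 0.05,
                    seed = 13)
  ld <- ld_matrix(simulate_genotypes(cfg))
  expect_equal(ld, t(ld))
  expect_equal(unname(diag(ld)), rep(1, 20))
  expect_true(all(ld >= 0 & ld <= 1, na.rm = TRUE))
})

test_that("LD expansion is single-hop with a strict threshold", {
  ld <- matrix(c(1, 0.9, 0.5,
                 0.9, 1, 0.9,
                 0.5, 0.9, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # b qualifies via a; c only via b, and proxies of proxies are not added
  expect_setequal(expand_by_ld("a", ld, threshold = 0.8), c("a", "b"))
  expect_setequal(expand_by_ld("a", ld, threshold = 1.0), "a")
  expect_setequal(expand_by_ld("a", ld, threshold = 0.9, strict = FALSE),
                  c("a", "b"))
  expect_equal(expand_by_ld(character(), ld), character())
  expect_error(expand_by_ld("zz", ld), "absent")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  expect_equal(hypergeom_enrichment(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_enrichment(0, 5, 5, 10), 1)
  set.seed(41)
  for (i in 1:300) {
    N <- sample(2:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(hypergeom_enrichment(k, K, n, N), hyper_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment(6, 5, 5, 10), "overlap")
})

test_that("cross-dataset sharing partitions probes with conserved counts", {
  ours <- tibble::tibble(probe_id = paste0("p", 1:4),
                         gene_symbol = paste0("G", 1:4),
                         snp_id = paste0("rs", 1:4))
  # verbatim copies: everything lands in all_three
  rep_all <- share_across_datasets(ours, ours, ours)
  expect_equal(tidy(rep_all)$count, c(4, 0, 0, 0))
  expect_equal(tidy(rep_all)$percent[1], 100)
  # empty externals: everything unique
  empty <- ours[0, c("gene_symbol", "snp_id")]
  rep_none <- share_across_datasets(ours, empty, empty)
  expect_equal(tidy(rep_none)$count, c(0, 0, 0, 4))
  # LD-proxy match: external reports a different SNP in strong LD
  ld <- matrix(c(1, 0.85, 0.85, 1), 2, 2,
               dimnames = list(c("rs1", "rsX"), c("rs1", "rsX")))
  ext <- tibble::tibble(gene_symbol = "G1", snp_id = "rsX")
  rep_ld <- share_across_datasets(ours, ext, empty, ld = ld)
  expect_equal(tidy(rep_ld)$count, c(0, 1, 0, 3))
  # partition always sums to the total
  expect_equal(sum(tidy(rep_ld)$count), rep_ld$total)
})

test_that("the Venn report reproduces printed percentages from counts", {
  rep <- overlap_report(248, 159, 28, 536)
  expect_equal(rep$total, 971)
  expect_equal(tidy(rep)$percent, c(25.54, 16.37, 2.88, 55.20))
  g <- glance(rep)
  expect_equal(g$shared_with_monocytes, 407)
  expect_equal(g$shared_with_bcells, 276)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("GWAS-catalog intersection counts overlaps per trait exactly", {
  # 20 catalog SNPs across 3 traits with known containment
  catalog <- tibble::tibble(
    snp_id = paste0("rs", 1:20),
    trait = rep(c("crohns", "psoriasis", "asthma"), length.out = 20))
  expanded <- paste0("rs", 1:6)    # traits get 2 hits each by construction
  hits <- gwas_intersect(expanded, catalog)
  expect_equal(nrow(hits), 3)
  expect_equal(sort(hits$n_overlap), c(2, 2, 2))
  orc <- sapply(split(catalog$snp_id, catalog$trait),
                function(s) length(intersect(s, expanded)))
  expect_equal(hits$n_overlap[order(hits$trait)], unname(orc[order(names(orc))]))
  # enrichment agrees with the enumeration oracle
  h <- hits[hits$trait == "crohns", ]
  expect_equal(h$p_enrichment,
               hyper_oracle(h$n_overlap, h$n_trait_snps, 6, 20))
  # degenerate inputs
  expect_equal(nrow(gwas_intersect(character(), catalog)), 0)
  expect_warning(gwas_intersect(expanded,
                                rbind(catalog,
                                      tibble::tibble(snp_id = NA,
                                                     trait = "x"))),
                 "malformed")
})

test_that("homolog mapping joins, reports unmapped, and rejects conflicts", {
  tab <- tibble::tibble(mouse = c("Il18rap", "Nod2"),
                        human = c("IL18RAP", "NOD2"))
  res <- map_homologs(c("Il18rap", "Nod2", "Gm123"), tab)
  expect_equal(res$mapped$mapped, c("IL18RAP", "NOD2"))
  expect_equal(res$unmapped, "Gm123")
  # identity table maps everything to itself
  idt <- tibble::tibble(a = c("X", "Y"), b = c("X", "Y"))
  expect_equal(map_homologs(c("X", "Y"), idt)$mapped$mapped, c("X", "Y"))
  # empty table maps nothing
  expect_equal(map_homologs("X", idt[0, ])$unmapped, "X")
  conflict <- tibble::tibble(a = c("X", "X"), b = c("Y", "Z"))
  expect_error(map_homologs("X", conflict), "X")
})
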