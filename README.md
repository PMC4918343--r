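# neutroqtl

Genome-wide *cis*-eQTL mapping for purified immune-cell transcriptomes,
with permutation-calibrated significance — plus the surrounding pipeline:
microarray-style quality control and quantile normalization, genotypic-LD
proxy expansion, cross-dataset eQTL sharing with hypergeometric enrichment,
GWAS-catalog intersection, and genotype-stratified qPCR response
statistics. A synthetic-data generator with known ground truth (LD blocks,
minor-allele-frequency spectrum, additive cis effects of controlled
variance explained) makes every stage testable without any external
download.

The package is written for analysts mapping expression quantitative trait
loci in a single purified cell subset — the motivating setting is
neutrophils isolated from a cohort of 114 donors — where the phenotype is a
samples × probes expression matrix and the genotypes are array allele
counts.

## The method

For a probe with expression vector *y* and a SNP with allele counts
*g* ∈ {0, 1, 2} (missing calls excluded pairwise), the association is the
ordinary least-squares fit

  *y* = α + β·*g* + ε,

tested with the two-sided *t*-test on β (*n* − 2 df). The variance
explained is *r*² = cor(*g*, *y*)². Only SNPs within ±250 kbp of the probe
midpoint are tested (closed interval).

Because each probe is tested against many correlated cis SNPs, nominal
p-values are calibrated per probe by phenotype permutation (label
swapping): for each of *B* permutations the expression vector is shuffled
once and tested against all cis SNPs, and the minimum nominal p across
SNPs is recorded. The probe's significance threshold is the α tail of
these *B* minima — the ⌈α·B⌉-th smallest, i.e. the 10th smallest of
10,000 at the default α = 0.001 — and a pair is significant when its
nominal p is strictly below its probe's threshold. Sharing one permutation
across the probe's SNPs preserves their LD, so the min-p null accounts for
the effective (not nominal) multiplicity.

Downstream, eQTL SNP sets are expanded by genotypic LD (squared Pearson
correlation of allele counts, one hop, *r*² > 0.8), compared against
external eQTL lists (shared when the matching gene carries the same SNP or
an LD proxy at *r*² ≥ 0.8), and intersected with a GWAS catalog; overlap
significance uses the upper-tail hypergeometric probability computed in
log space. Stimulation-response validation uses ΔCt = Ct(gene) −
Ct(control), linear expression 2^(−ΔCt), fold change
2^(ΔCt_mock − ΔCt_treated), and Mann–Whitney (two genotype groups, exact
in the small-sample regime) or Kruskal–Wallis with Dunn's post-hoc tests
(three groups).

## Worked example

```r
library(neutroqtl)
library(dplyr)

cfg <- sim_config(n_samples = 114, n_snps = 50, n_probes = 10,
                  ld_block_size = 5, n_effects = 3, target_r2 = 0.5,
                  missing_rate = 0.02, seed = 42)
gp  <- simulate_genotypes(cfg)          # 114 donors, block-LD genotypes
sim <- simulate_expression(gp, cfg)     # 3 true effects, each r2 = 0.5
res <- map_cis_eqtl(gp, sim$expression, n_perm = 1000, alpha = 0.001,
                    seed = 42)
res
#> <eqtl_result> 50 pairs tested across 10 probes; 11 significant pairs on 3 probes

tidy(res) |> filter(significant) |> arrange(p_nominal) |>
  select(probe_id, snp_id, distance, n_used, beta, r2, p_nominal,
         p_threshold) |> head(5)
#> # A tibble: 5 × 8
#>   probe_id   snp_id distance n_used  beta    r2 p_nominal p_threshold
#>   <chr>      <chr>     <dbl>  <int> <dbl> <dbl>     <dbl>       <dbl>
#> 1 probe_0002 rs0008        0    113 2.58  0.491  5.80e-18   0.000129
#> 2 probe_0001 rs0003        0    114 2.04  0.475  2.37e-17   0.000212
#> 3 probe_0003 rs0013        0    113 1.17  0.415  1.42e-14   0.0000669
#> 4 probe_0003 rs0012    -5000    113 0.942 0.269  3.95e- 9   0.0000669
#> 5 probe_0003 rs0011   -10000    110 0.986 0.238  6.55e- 8   0.0000669
```

All three probes given a true effect are recovered (`r2` near the
simulated 0.5 at the causal SNP, attenuated at its LD proxies; the seven
null probes stay below their permutation thresholds). `autoplot(res)`
draws the Manhattan-style view; `glance(res)` returns the pair, probe and
gene counts as one row.

A full run — simulate, QC, normalize, map, overlap, GWAS intersect, with
every artifact written to a directory and a count ledger in `log.json` —
is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), "runs/demo")
```

or from a shell, `Rscript inst/scripts/neutroqtl-pipeline.R --out runs/demo
--seed 1`.

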