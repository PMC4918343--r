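---
title: "Permutation-calibrated cis-eQTL mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-calibrated cis-eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutroqtl)
library(dplyr)
```

## The model and its assumptions

An expression quantitative trait locus (eQTL) analysis asks, for each
expression probe, whether nearby genetic variation shifts the probe's
measured expression. The additive model used throughout this package is

$$y_i = \alpha + \beta g_i + \varepsilon_i, \qquad
  g_i \in \{0, 1, 2\},\ \varepsilon_i \sim N(0, \sigma^2),$$

where $g_i$ is the allele count of sample $i$ at the SNP (homozygotes 0
and 2, heterozygotes 1) and $y_i$ is log2-scale expression. The fit is
ordinary least squares; the reported p-value is the two-sided $t$-test on
$\beta$ with $n-2$ degrees of freedom, and the variance explained is the
squared Pearson correlation $r^2 = \mathrm{cor}(g, y)^2$. Samples missing
the genotype at a SNP are excluded pairwise, per SNP–probe pair, so one
bad assay does not shrink the whole analysis.

The additive coding assumes allele dosage acts linearly on log2
expression; dominance and interaction effects are absorbed into the
residual. No covariates are fitted — the intended setting is a
single-cell-type, single-population cohort where expression principal
components and sex carry little of the cis signal; regressing them out is
deliberately out of scope.

### Why permutation thresholds

A probe is tested against every SNP within its cis window, and those SNPs
are correlated through linkage disequilibrium (LD), so Bonferroni-style
corrections on the SNP count are badly miscalibrated. The package instead
permutes the phenotype: within one permutation the expression vector is
shuffled once and tested against *all* cis SNPs of the probe, and the
minimum nominal p across SNPs is recorded. Shuffling the phenotype (not
the genotypes) preserves the LD among SNPs, so the distribution of minima
reflects the probe's effective multiplicity. The significance threshold is
the $\alpha$ tail of the $B$ minima, taken as the
$\lceil \alpha B \rceil$-th smallest without interpolation — the 10th
smallest of 10,000 at the defaults — a deliberately conservative order
statistic. A pair is called significant when its nominal p is *strictly*
below its probe's threshold, so a pair exactly at the threshold is not
called. Two perfectly correlated cis SNPs give bit-identical min-p
distributions to a single SNP: the calibration sees effective, not
nominal, multiplicity.

Permutations are label swaps under a deterministic per-probe random
stream derived from the run seed and the probe id, so serial and parallel
executions (and probe subsets) reproduce identical thresholds. Missing
genotypes under permutation are handled exactly as in the unpermuted
analysis: labels are swapped first, then pairwise deletion is applied per
SNP.

p-values are also reported as `log10_p`, computed from the $t$ survival
function in log space, so that associations too strong for double
precision (nominal p underflowing to zero) remain ordered and finite.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 250,000 | bp | cis window half-width around the probe midpoint; closed interval, so a SNP at exactly 250 kbp is tested |
| `n_perm` | 10,000 | permutations | resolution of the min-p null; the smallest attainable threshold is the 1/`n_perm` quantile |
| `alpha` | 0.001 | fraction | tail of the min-p distribution used as the per-probe threshold |
| `min_call_rate` | 0.95 | fraction | SNPs with a lower fraction of non-missing calls are removed; exactly 95% is retained |
| `min_detection` | 0.05 | fraction | probes detected in fewer samples are flagged, never removed |
| `dup_r2` | 0.98 | $r^2$ | expression correlation above which two samples are treated as duplicates |
| `ld_threshold` | 0.8 | $r^2$ | LD level treated as "the same signal" across SNPs |

Two LD comparisons intentionally differ: proxy *expansion* uses strictly
greater than the threshold ("exceeding 0.8"), while cross-dataset
*sharing* uses greater-or-equal ("threshold of 0.8"); both expose the flag.

## What the generator emulates — and what it does not

`simulate_genotypes()` draws, per SNP, a minor allele frequency uniformly
within `maf_range`, then generates a latent Gaussian AR(1) process within
each LD block (adjacent correlation `ld_decay`, decaying as
`ld_decay^distance`) and thresholds it at the Hardy–Weinberg cutpoints
$q^2$ and $q^2 + 2pq$. This yields genotypes that are individually
Hardy–Weinberg consistent with tunable genotypic $r^2$ between
neighbours — the two properties the association and LD machinery actually
consume. Missing calls are masked completely at random, matching the
pairwise-deletion contract being tested.

`simulate_expression()` adds to Gaussian log2-scale noise an effect
$\beta g$ with $\beta$ solved from the requested variance explained:
$\beta = \sigma \sqrt{v/(1-v)} / \mathrm{sd}(g)$, using the empirical
genotype standard deviation of the draw, so the realized $r^2$ is centred
on the target $v$ at any cohort size. When `noise_sd = 0` the ratio is
degenerate (any $\beta > 0$ gives $r^2 = 1$) and $\beta$ is set to 1.
Missing genotypes are mean-imputed for phenotype generation only — the
ground-truth effect acts on the donor's true dosage; the analysis side
never sees the imputation.

The defaults are the study conditions of the emulated cohort: 114
samples, a 0.05–0.5 allele-frequency spectrum, unit log2 noise, and
effects spanning the 0–0.8 variance-explained range seen for strong cis
signals. What the generator does *not* emulate: haplotype phase and
recombination maps, population structure and admixture, probe
cross-hybridization, batch and hybridization-date effects, and the heavy
inter-probe correlation of real transcriptomes. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under
clean MCAR, HWE, block-LD conditions — not that the pipeline is robust to
structured artefacts in real array data, which is what the QC stage
exists to catch.

Detection calls are an external input in real data (the platform's
detection p-values); `simulate_detection_calls()` fabricates them as
Bernoulli draws because only the flagging rule — fraction detected below
5%, flag but never remove — is under test.

## Numerical and procedural choices

* **Quantile normalization** (via `limma::normalizeQuantiles`, ties
  averaged): ties receive the mean of the reference values at their tied
  ranks — the common convention; the array vendor's exact tie dialect is
  unspecified upstream. Background subtraction is not applied.
* **QC precedence**: a SNP failing several filters is counted once, under
  the first failing rule in the fixed order non-autosome → call-rate →
  monomorphic, making report counts deterministic. "Monomorphic" means
  one distinct observed genotype; no additional MAF filter is applied to
  analysis SNPs.
* **Boundaries**: call rate exactly at 95% is retained (only "< 95%" is
  removed); the cis window is closed at exactly ±250 kbp; significance is
  a strict inequality at the permutation threshold.
* **Genotypic LD**: squared Pearson correlation of allele counts over
  pairwise-complete samples — the standard phase-free proxy for haplotype
  $r^2$; constant vectors give undefined LD, reported `NA` and treated as
  below any threshold. Proxy expansion is one hop, never transitive
  closure, matching tagSNP usage.
* **Hypergeometric enrichment** is the upper tail $P(X \ge k)$ computed
  in log space (`stats::phyper(log.p = TRUE)`), so $10^{-100}$-scale
  enrichments survive.
* **Rank tests**: the two-group comparison uses the exact Mann–Whitney
  distribution when the combined $n \le 20$ with no ties (the qPCR
  validation cohorts, 7–9 donors per genotype, sit squarely in this
  regime) and the normal approximation with continuity correction
  otherwise. Dunn's post-hoc $z$-tests use mid-ranks with tie-corrected
  variance; the multiplicity adjustment defaults to Bonferroni with a
  flag for unadjusted, since the original post-hoc software offers both.
* **Degenerate pairs**: a genotype constant after pairwise deletion, or
  fewer than three usable samples, makes the association undefined; such
  pairs are skipped and logged rather than fitted.

## Genuinely open choices, decided here

* Whether one permutation set should be shared across probes was open;
  this package derives an independent stream per probe from
  `(seed, probe_id)`, which keeps probes independent and makes partial
  re-runs reproducible.
* Enrichment universes for the sharing and GWAS analyses are not fixed by
  convention; the defaults are the total tested probes and the distinct
  catalog SNPs respectively, both overridable, and the package treats the
  resulting p-values as configurable summaries rather than reproduction
  targets.
* Cross-dataset matching supports both gene-symbol and probe-id keys;
  gene symbol is the default for external lists, since external studies
  rarely share a probe design.
* The pipeline removes the *second* sample of each detected duplicate
  pair (row order), a deterministic tie-break.

## Problem sizes in the shipped tests

The test suite exercises the calibration claims at sizes chosen to give
tight Monte-Carlo error while keeping a default run in minutes:
closed-form OLS agreement on 1,000 random instances at $10^{-10}$
relative tolerance; permutation false-positive rate on 2,000 null probes
(n = 114, 1,000 permutations, $\alpha = 0.05$) within three binomial
standard deviations; variance-explained recovery (target 0.70, n = 114)
averaged over 100 replicates within ±0.05; exhaustive hypergeometric
enumeration for every universe up to 30; exhaustive Mann–Whitney
enumeration for all group sizes with $n_1 + n_2 \le 10$; and
Kruskal–Wallis null size over 2,000 simulations. Larger runs only shrink
the Monte-Carlo error around the same targets.

## Known limitations

Trans effects, covariate adjustment, beta-approximated permutation
p-values, haplotype-aware LD and probe re-mapping are out of scope.
The permutation engine is $O(B \cdot m \cdot n)$ per probe ($m$ cis
SNPs); at the default 10,000 permutations a genome-wide run is an
overnight batch, and `n_perm` should be reduced for interactive
exploration. The generator's flat MAF spectrum is conventional rather
than matched to any specific population, and conclusions about power at
rare MAF should be drawn from purpose-built configs rather than the
defaults.
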