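# Independent oracles, kept deliberately naive: closed-form OLS from sums,
# exhaustive enumeration for rank tests and hypergeometric tails. They never
# call the package code paths they check.

ols_oracle <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  n <- length(g)
  sxx <- sum((g - mean(g))^2)
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  se <- sqrt((syy - beta * sxy) / (n - 2) / sxx)
  tt <- beta / se
  list(n_used = n, beta = beta, r2 = sxy^2 / (sxx * syy),
       p = 2 * stats::pt(-abs(tt), n - 2))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups; doubles the tail containing the observed
# U statistic (U = number of (x, y) pairs with x > y), capped at 1.
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) sum(outer(pool[idx], pool[-idx], ">"))
  u_obs <- u_of(seq_len(nx))
  us <- utils::combn(nx + ny, nx, u_of)
  m <- nx * ny
  p <- if (u_obs > m / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# Upper-tail hypergeometric by direct summation of the pmf.
hyper_oracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# small genotype vector from Hardy-Weinberg frequencies
hw_genotypes <- function(n, maf) {
  sample(0:2, n, replace = TRUE, prob = c((1 - maf)^2, 2 * maf * (1 - maf),
                                          maf^2))
}
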