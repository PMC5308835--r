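# Independent oracle implementations used to cross-check the package's
# computational paths. Deliberately coded from first principles (sums,
# binomial coefficients, quadrature) rather than through the library calls
# the implementation itself uses.

# textbook Pearson formula over pairwise-complete positions
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# right-tail hypergeometric probability by exhaustive enumeration of all
# 2x2 tables with the observed margins
oracle_fisher_right <- function(a, b, c, d) {
  K <- a + c   # focus genes
  M <- b + d   # non-focus genes
  n <- a + b   # network size
  ks <- max(0L, n - M):min(K, n)
  probs <- choose(K, ks) * choose(M, n - ks) / choose(K + M, n)
  sum(probs[ks >= a])
}

# two-sided correlation p-value by numerical integration of the t density
oracle_p_quadrature <- function(r, n) {
  df <- n - 2
  t_obs <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::integrate(function(u) stats::dt(u, df), t_obs, Inf,
                       rel.tol = 1e-12)$value
}
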