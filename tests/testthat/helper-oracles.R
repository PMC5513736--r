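# Independent brute-force oracles. These deliberately avoid the code paths
# used by the package (pbinom's incomplete beta, fisher.test, phyper):
# everything here is direct log-space PMF summation over the support.

# P(X <= k), X ~ Binomial(n, p), by compensated summation of PMF terms
oracle_binom_cdf <- function(k, n, p) {
  j <- 0:k
  terms <- exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p))
  s <- 0; comp <- 0
  for (t in terms) {
    y <- t - comp
    tt <- s + y
    comp <- (tt - s) - y
    s <- tt
  }
  min(1, s)
}

oracle_binom_upper <- function(k, n, p) {
  if (k == 0) return(1)
  1 - oracle_binom_cdf(k - 1, n, p)
}

# two-sided Fisher P by full enumeration over the hypergeometric support,
# summing outcomes no more probable than the observed table (with the
# customary 1 + 1e-7 relative tolerance for ties)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  x <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  prob <- exp(logp)
  obs <- prob[x == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# P(X >= overlap) for the set-overlap hypergeometric, by direct
# combinatorial enumeration with exact binomial coefficients
oracle_hypergeom_upper <- function(overlap, size_a, size_b, universe) {
  j <- overlap:min(size_a, size_b)
  sum(choose(size_a, j) * choose(universe - size_a, size_b - j)) /
    choose(universe, size_b)
}

# hand-rolled BH step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}
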