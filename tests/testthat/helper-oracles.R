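# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route than the implementation (brute-force
# enumeration, dense-grid direct computation, analytic formulas), so a
# shared bug cannot cancel.

# Dense-grid MAF posterior computed directly (default 1e-5 resolution).
# Returns the grid argmax and equal-tailed interval from the raw
# binomial likelihood with error folding.
oracle_grid_posterior <- function(k, n, e, res = 1e-5, level = 0.95) {
  f <- seq(0, 1, by = res)
  ll <- dbinom(k, n, f * (1 - e) + (1 - f) * e, log = TRUE)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cdf <- cumsum(w)
  a <- (1 - level) / 2
  list(map = f[which.max(w)],
       ci_low = f[which(cdf >= a)[1]],
       ci_high = f[which(cdf >= 1 - a)[1]])
}

# Dense-grid amplicon posterior with the error rate marginalized by the
# same midpoint-quantile rule but computed straightforwardly in
# probability space at high resolution.
oracle_pasm_posterior <- function(k, n, alpha, beta, nodes = 32,
                                  res = 1e-5) {
  f <- seq(0, 1, by = res)
  e <- qbeta((seq_len(nodes) - 0.5) / nodes, alpha, beta)
  lik <- rowMeans(sapply(e, function(ej) {
    dbinom(k, n, f * (1 - ej) + (1 - f) * ej)
  }))
  w <- lik / sum(lik)
  cdf <- cumsum(w)
  list(map = f[which.max(w)],
       ci_low = f[which(cdf >= 0.025)[1]],
       ci_high = f[which(cdf >= 0.975)[1]])
}

# Two-sided Fisher p by literal enumeration: every admissible table with
# the observed margins, probabilities from choose() directly.
oracle_fisher_enum <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  N <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  prob <- choose(m1, xs) * choose(m2, k - xs) / choose(N, k)
  p_obs <- prob[xs == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Analytic variance of the alt-read fraction under the two-stage model:
# template draw Binomial(N, f) then reads Binomial(n, m/N), error-free.
oracle_two_stage_var <- function(f, N, n) {
  # Var = E[Var(k/n | m)] + Var(m/N)
  f * (1 - f) * (1 / N + (1 - 1 / N) / n)
}
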