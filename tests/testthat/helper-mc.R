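# Monte-Carlo helpers shared by the simulation-based tests.

# binomial Monte-Carlo standard error at a target rate
binom_mcse <- function(p, n) sqrt(p * (1 - p) / n)

# Empirical rejection rates of GMP thresholds over independent-uniform
# replicates, computed in chunks so K = 1000 x 1e5 never materializes at
# once.  Returns a data.frame over the (r, eps) grid; the same uniforms are
# reused for every exponent, which only sharpens the comparison.
gmp_null_rejection_rates <- function(rs, K, nrep, epss, chunk = 5000L,
                                     threshold_fun = function(r, eps) {
                                       gclt_threshold(r, K, eps)$psi
                                     }) {
  sums <- matrix(0, nrep, length(rs))
  done <- 0L
  while (done < nrep) {
    m <- min(chunk, nrep - done)
    P <- matrix(runif(m * K), m, K)
    for (j in seq_along(rs)) {
      sums[done + seq_len(m), j] <- rowSums(P^rs[j])
    }
    done <- done + m
  }
  out <- expand.grid(r = rs, eps = epss)
  out$rate <- mapply(function(r, eps) {
    psi <- threshold_fun(r, eps)
    j <- match(r, rs)
    # M <= psi  <=>  sum p^r >= K psi^r for r < 0, <= for r > 0
    if (r < 0) mean(sums[, j] >= K * psi^r) else mean(sums[, j] <= K * psi^r)
  }, out$r, out$eps)
  out
}

# brute-force Simes statistic, independent of the package implementation
simes_brute <- function(p) {
  K <- length(p)
  ps <- sort(p)
  best <- Inf
  for (i in seq_len(K)) best <- min(best, K * ps[i] / i)
  best
}
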