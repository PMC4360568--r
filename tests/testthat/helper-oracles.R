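# Independent oracles the tests check the implementation against.

# Poisson mass from first principles: exact integer factorial, no dpois.
poisson_pmf_oracle <- function(k, lambda) {
  exp(-lambda) * lambda^k / factorial(k)
}

# Truncation-equilibrium loss by direct summation over Poisson terms,
# solving conditional-mean = M with fractional acceptance at the
# threshold. Independent of the package solver (scans every threshold,
# uses the oracle pmf).
truncation_loss_oracle <- function(M, N, k_max = 200) {
  k <- 0:k_max
  p <- poisson_pmf_oracle(k, M + N)
  for (K in 1:k_max) {
    below <- k < K
    S0 <- sum(p[below]); S1 <- sum(k[below] * p[below])
    a <- (M * S0 - S1) / (p[K + 1] * (K - M))
    if (is.finite(a) && a >= 0 && a <= 1) {
      return(list(k_star = K, accept = a, loss = 1 - (S0 + a * p[K + 1])))
    }
  }
  stop("oracle failed")
}

# Wilson-free binomial band: 3 standard errors around an expectation.
within_3se <- function(estimate, expected, se) {
  abs(estimate - expected) <= 3 * se
}
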