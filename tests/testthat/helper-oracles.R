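# Independent brute-force oracles used to pin down the vectorized
# implementations, plus small fixture builders.

# Topological overlap by explicit triple loop over the formula
# omega_ij = (a_ij + u_ij) / (min(m_i, m_j) + 1 - a_ij)
tom_bruteforce <- function(A) {
  n <- nrow(A)
  diag(A) <- 0
  W <- matrix(1, n, n)
  m <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- 0
    for (k in seq_len(n)) if (k != i && k != j) u <- u + A[i, k] * A[k, j]
    W[i, j] <- (A[i, j] + u) / (min(m[i], m[j]) + 1 - A[i, j])
  }
  W
}

# Monotonicity statistic by explicit double loop over ordered pairs
monotonicity_bruteforce <- function(s, tie_eps = 1e-9) {
  n <- length(s)
  tot <- 0
  for (j in 2:n) for (i in 1:(j - 1)) {
    d <- s[j] - s[i]
    tot <- tot + if (abs(d) <= tie_eps) 0 else sign(d)
  }
  2 / (n * (n - 1)) * tot
}

# 1-D EMD as total |CDF difference| x bin width on a fixed binning
emd_cdf_oracle <- function(a, b, breaks) {
  nb <- length(breaks) - 1L
  ha <- hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
  hb <- hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
  sum(abs(cumsum(ha) - cumsum(hb))) * diff(breaks)[1]
}

# Log prior-predictive density of a single observation under the
# normal-gamma model: a generalized Student-t with df = 2*alpha0,
# location mu0, scale^2 = beta0 * (kappa0 + 1) / (alpha0 * kappa0)
student_t_log_predictive <- function(v, prior) {
  nu <- 2 * prior$alpha0
  sc <- sqrt(prior$beta0 * (prior$kappa0 + 1) / (prior$alpha0 * prior$kappa0))
  stats::dt((v - prior$mu0) / sc, df = nu, log = TRUE) - log(sc)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small default-shaped bundle for fast tests
small_bundle <- function(seed = 1, ...) {
  generate_bundle(synth_config(n_genes = 80L, n_samples_resistant = 30L,
                               n_samples_sensitive = 30L, n_modules = 3L,
                               module_size_range = c(10L, 14L),
                               n_modulators = 6L,
                               n_passenger_long_genes = 8L,
                               seed = seed, ...))
}
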