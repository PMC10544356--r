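# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (quadrature, direct scans) rather than
# calling the code paths they check.

# step-up BY adjustment by a direct min-over-j scan of the definition
brute_force_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q[o[i]] <- min(1, min(m * cm * ps[j] / j))
  }
  q
}

# sup |ECDF - F| by scanning every jump of the empirical CDF
brute_force_ks_D <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

# first three central moments of a density by adaptive quadrature,
# expressed as (mean, sd, skewness)
moments_by_quadrature <- function(dens, lower = -Inf, upper = Inf) {
  m1 <- stats::integrate(function(x) x * dens(x), lower, upper,
                         rel.tol = 1e-11)$value
  v <- stats::integrate(function(x) (x - m1)^2 * dens(x), lower, upper,
                        rel.tol = 1e-11)$value
  m3 <- stats::integrate(function(x) (x - m1)^3 * dens(x), lower, upper,
                         rel.tol = 1e-11)$value
  list(mu = m1, sigma = sqrt(v), gamma = m3 / v^1.5)
}

# random valid centered parameter triples, away from the skewness boundary
random_cp <- function(n, gamma_frac = 0.9) {
  k <- sn_skewness_bound()
  list(
    mu = stats::runif(n, -5, 5),
    sigma = stats::runif(n, 0.2, 3),
    gamma = stats::runif(n, -gamma_frac * k, gamma_frac * k)
  )
}

# skew-normal sampler driven by centered parameters
rsn_cp <- function(n, mu, sigma, gamma) {
  dp <- cp_to_dp(mu, sigma, gamma)
  rsn(n, dp$xi, dp$omega, dp$alpha)
}
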