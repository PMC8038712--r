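# Shared fixtures and independent oracles, all built in code.

# Spectrum of Gaussian bands on a grid (independent of the simulate module).
gaussian_spectrum <- function(grid, centers, sigmas, amps, ...) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-(grid - centers[i])^2 / (2 * sigmas[i]^2))
  }
  spectrum(grid, y, ...)
}

# Analytic second derivative of a sum of Gaussians.
gaussian_d2 <- function(x, centers, sigmas, amps) {
  y <- numeric(length(x))
  for (i in seq_along(centers)) {
    d <- x - centers[i]; s2 <- sigmas[i]^2
    y <- y + amps[i] * (d^2 / s2^2 - 1 / s2) * exp(-d^2 / (2 * s2))
  }
  y
}

# Brute-force exact two-sided Mann-Whitney p by full enumeration of rank
# assignments: P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|).
mw_exact_p_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  ranks <- seq_len(N)  # tie-free: pooled ranks are 1..N
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  c_mid <- n1 * n2 / 2
  mean(abs(u_all - c_mid) >= abs(u_obs - c_mid) - 1e-9)
}

# Tiny deterministic spectra set for PCA fixtures.
toy_set <- function(n = 6, p = 40, seed = 42) {
  set.seed(seed)
  grid <- seq(1000, 1000 + 2 * (p - 1), by = 2)
  m <- matrix(rnorm(n * p), n, p)
  spectra_set(grid, m, sample_ids = sprintf("s%d", 1:n),
              groups = rep(c("A", "B"), length.out = n))
}
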