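# Independent dense oracles used across tests.  These deliberately use only
# base linear algebra on explicitly formed covariance matrices, so they stay
# independent of the factorized code paths they check.

# exponential-kernel covariance with the same fixed diagonal jitter the
# structures use
dense_K <- function(S, alpha, jitter = 1e-8) {
  K <- exp(-as.matrix(dist(S)) / alpha)
  diag(K) <- diag(K) + jitter
  K
}

# multivariate normal log density via solve(), no Cholesky reuse
dense_mvn_logdens <- function(w, K) {
  n <- length(w)
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(K, logarithm = TRUE)$modulus +
                       crossprod(w, solve(K, w))))
}

random_sites <- function(n) cbind(runif(n), runif(n))

# knot set located exactly at the sites (GPP interpolation limit)
knots_at_sites <- function(S)
  structure(list(knots = S, m_star = nrow(S), spacing = NA),
            class = "knot_set")

# Monte Carlo standard error of a sample mean
mc_se <- function(x) sd(x) / sqrt(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick small community fit used by several method tests
tiny_fit <- function(seed = 1, spatial = "nngp", n_iter = 120, m = 4,
                     family = "probit", ...) {
  sim <- simulate_community(n_sites = 48, n_species = 3, n_cov = 2,
                            n_factors = 2, alpha = 0.3, family = family,
                            seed = seed)
  spjsdm(sim$train, spatial = spatial, m = m, n_factors = 2,
         n_iter = n_iter, n_burn = n_iter / 2, seed = seed, ...)
}
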