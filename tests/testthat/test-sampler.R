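# Conditional-correctness checks: each Gibbs block, run repeatedly with the
# rest of the state frozen, must reproduce its analytically known conditional
# moments (Monte Carlo tolerance, small dense instances).

test_that("probit augmentation respects truncation and tail safety", {
  set.seed(20)
  Y <- matrix(rbinom(40, 1, 0.5), 10, 4)
  L <- matrix(rnorm(40), 10, 4)
  Z <- matrix(0, 10, 4)
  for (r in 1:20) {
    Z <- spjsdm:::.update_Z(Z, Y, L, 1:4)
    expect_true(all(Z[Y == 1] > 0))
    expect_true(all(Z[Y == 0] <= 0))
  }
  # half-normal mean at L = 0, Y = 1
  n_mc <- 1e5
  z <- spjsdm:::.rtnorm_half(rep(0, n_mc), rep(TRUE, n_mc))
  expect_lt(abs(mean(z) - sqrt(2 / pi)), 3 * mc_se(z))
  # far-tail truncation stays finite and respects the bound
  zt <- spjsdm:::.rtnorm_half(rep(-10, 1000), rep(TRUE, 1000))
  expect_true(all(is.finite(zt) & zt > 0))
  zt2 <- spjsdm:::.rtnorm_half(rep(30, 500), rep(FALSE, 500))
  expect_true(all(is.finite(zt2) & zt2 <= 0))
})

test_that("beta conditional matches the GLS closed form", {
  set.seed(21)
  n <- 30; nc <- 2
  X <- cbind(1, rnorm(n))
  eta <- matrix(0, n, 1); lambda <- matrix(0, 1, 1)
  Tmat <- matrix(1, 1, 1); gamma <- matrix(0, nc, 1)
  sigma2 <- 1.3
  Z <- matrix(rnorm(n, mean = X %*% c(0.5, -1)), n, 1)
  priors <- spjsdm_priors(beta_var = 100)   # flat-ish
  Vm <- spjsdm:::.beta_prior_matrices(priors, nc)
  # analytic conditional moments
  Q <- Vm$Vinv + crossprod(X) / sigma2
  mean_or <- solve(Q, crossprod(X, Z) / sigma2)
  n_mc <- 1e4
  draws <- matrix(0, n_mc, nc)
  for (r in seq_len(n_mc))
    draws[r, ] <- spjsdm:::.update_beta_gamma(Z, X, eta, lambda, Tmat, gamma,
                                              sigma2, priors, Vm)$beta
  covd <- solve(Q)
  for (k in 1:nc)
    expect_lt(abs(mean(draws[, k]) - mean_or[k]),
              3 * sqrt(covd[k, k] / n_mc))
  expect_lt(max(abs(cov(draws) - covd)), 4 * max(covd) / sqrt(n_mc))
})

test_that("beta conditional collapses to the prior when uninformative", {
  set.seed(22)
  n <- 10
  X <- cbind(1, rnorm(n))
  eta <- matrix(0, n, 1); lambda <- matrix(0, 1, 1)
  Tmat <- matrix(1, 1, 1)
  Z <- matrix(rnorm(n, 5), n, 1)
  # prior variance -> 0 with prior mean 0 (gamma frozen at 0): beta ~ 0
  pr0 <- spjsdm_priors(beta_var = 1e-10, gamma_var = 1e-10)
  Vm0 <- spjsdm:::.beta_prior_matrices(pr0, 2)
  b <- spjsdm:::.update_beta_gamma(Z, X, eta, lambda, Tmat,
                                   matrix(0, 2, 1), 1, pr0, Vm0)$beta
  expect_lt(max(abs(b)), 1e-3)
  # likelihood washout: sigma2 -> Inf leaves the proper prior
  pr1 <- spjsdm_priors(beta_var = 2, gamma_var = 1e-10)
  Vm1 <- spjsdm:::.beta_prior_matrices(pr1, 2)
  n_mc <- 4000
  d <- t(vapply(seq_len(n_mc), function(r)
    drop(spjsdm:::.update_beta_gamma(Z, X, eta, lambda, Tmat,
                                     matrix(0, 2, 1), 1e12, pr1,
                                     Vm1)$beta), numeric(2)))
  expect_lt(max(abs(colMeans(d))), 4 * sqrt(2 / n_mc))
  expect_lt(max(abs(apply(d, 2, var) - 2)), 4 * 2 * sqrt(2 / n_mc))
})

test_that("loading conditional matches the scalar conjugate formula", {
  set.seed(23)
  n <- 12
  eta <- matrix(rnorm(n), n, 1)
  X <- matrix(1, n, 1); beta <- matrix(0, 1, 1)
  Z <- matrix(rnorm(n, eta * 0.8), n, 1)
  phi <- matrix(2, 1, 1); tau <- 1.5; sigma2 <- 1
  prec <- phi[1] * tau + sum(eta^2) / sigma2
  m_or <- sum(eta * Z) / sigma2 / prec
  n_mc <- 1e4
  d <- vapply(seq_len(n_mc), function(r)
    spjsdm:::.update_lambda(Z, X, beta, eta, phi, tau, sigma2)[1, 1],
    numeric(1))
  expect_lt(abs(mean(d) - m_or), 3 * sqrt(1 / prec / n_mc))
  expect_lt(abs(var(d) - 1 / prec), 4 * (1 / prec) / sqrt(n_mc))
  # shrinkage domination
  dd <- spjsdm:::.update_lambda(Z, X, beta, eta, matrix(1e12, 1, 1), 1,
                                sigma2)
  expect_lt(abs(dd[1, 1]), 1e-4)
  # no information: eta = 0 leaves the prior N(0, 1/(phi tau))
  d0 <- vapply(seq_len(n_mc), function(r)
    spjsdm:::.update_lambda(Z, X, beta, 0 * eta, phi, tau, sigma2)[1, 1],
    numeric(1))
  expect_lt(abs(var(d0) - 1 / (phi[1] * tau)), 4 / (phi[1] * tau) / sqrt(n_mc))
})

test_that("shrinkage conditionals have the stated gamma laws", {
  set.seed(24)
  priors <- spjsdm_priors()
  # Lambda = 0: phi ~ Gamma((nu+1)/2, nu/2), mean (nu+1)/nu
  lam0 <- matrix(0, 2, 3)
  phis <- replicate(4000, spjsdm:::.update_shrinkage(lam0, c(1, 1),
                                                     priors)$phi[1, 1])
  expect_lt(abs(mean(phis) - (priors$nu + 1) / priors$nu),
            4 * mc_se(phis))
  # positivity of the global products every update
  lam <- matrix(rnorm(6), 2, 3)
  for (r in 1:50) {
    sh <- spjsdm:::.update_shrinkage(lam, runif(2, 0.5, 2), priors)
    expect_true(all(sh$phi > 0), all(sh$delta > 0), all(sh$tau > 0))
  }
  # single factor, single species: MC mean of phi matches 1-D quadrature of
  # p(phi) * N(lambda; 0, (phi tau)^-1)
  lam1 <- matrix(0.7, 1, 1); tau1 <- 1
  kern <- function(p) dgamma(p, priors$nu / 2, priors$nu / 2) *
    dnorm(lam1[1], 0, 1 / sqrt(p * tau1))
  Zc <- integrate(kern, 0, Inf)$value
  m_or <- integrate(function(p) p * kern(p), 0, Inf)$value / Zc
  d <- replicate(1e4, spjsdm:::.update_shrinkage(lam1, 1, priors)$phi[1, 1])
  expect_lt(abs(mean(d) - m_or), 3 * mc_se(d))
})

test_that("residual variance conditional is the conjugate inverse gamma", {
  set.seed(25)
  n <- 20
  Z <- matrix(rnorm(n, 0, 2), n, 1)
  L <- matrix(0, n, 1)
  priors <- spjsdm_priors(sigma2_shape = 2, sigma2_rate = 1)
  ss <- sum(Z^2)
  sh <- priors$sigma2_shape + n / 2
  ra <- priors$sigma2_rate + ss / 2
  d <- replicate(1e4, spjsdm:::.update_sigma2(Z, L, 1, 1, priors))
  expect_lt(abs(mean(d) - ra / (sh - 1)), 4 * mc_se(d))
  # residual-free limit concentrates near zero
  d0 <- replicate(2000, spjsdm:::.update_sigma2(0 * Z, L, 1, 1, priors))
  expect_lt(quantile(d0, 0.95), 10 * priors$sigma2_rate / sh)
  # probit species untouched
  s2 <- spjsdm:::.update_sigma2(Z, L, c(1, 1), integer(0), priors)
  expect_identical(s2, c(1, 1))
})

test_that("block eta update matches the dense Gaussian conditional", {
  set.seed(26)
  n <- 12; ns <- 3; nf <- 2
  S <- random_sites(n)
  lambda <- matrix(rnorm(nf * ns), nf, ns)
  sigma2 <- c(1, 1.5, 0.7)
  Rres <- matrix(rnorm(n * ns), n, ns)
  M <- lambda %*% diag(1 / sigma2) %*% t(lambda)
  b <- as.numeric((Rres %*% diag(1 / sigma2)) %*% t(lambda))
  alphas <- c(0.4, 0.15)
  g <- build_neighbor_graph(S, n - 1)
  kn <- knots_at_sites(S)
  backends <- list(
    gp = lapply(alphas, function(a) build_spatial_structure(S, "gp", a)),
    nngp = lapply(alphas, function(a)
      build_spatial_structure(S, "nngp", a, graph = g)),
    gpp = lapply(alphas, function(a)
      build_spatial_structure(S, "gpp", a, knots = kn)),
    mixed_iid = list(build_spatial_structure(S, "gp", alphas[1]),
                     build_spatial_structure(S, "iid")))
  for (nm in names(backends)) {
    structs <- backends[[nm]]
    Ks <- lapply(structs, spatial_covariance)
    P <- kronecker(M, diag(n))
    for (h in seq_len(nf)) {
      blk <- (h - 1) * n + seq_len(n)
      P[blk, blk] <- P[blk, blk] + solve(Ks[[h]])
    }
    res <- spjsdm:::.update_eta(Rres, lambda, sigma2, structs, moments = TRUE)
    expect_lt(max(abs(as.numeric(res$mean) - solve(P, b))), 1e-6)
    expect_lt(max(abs(res$cov - solve(P))), 1e-6)
  }
})

test_that("eta update falls back to the prior when the data are silent", {
  set.seed(27)
  n <- 5; S <- random_sites(n)
  st <- list(build_spatial_structure(S, "gp", 0.4))
  lambda <- matrix(0, 1, 2)
  Rres <- matrix(rnorm(n * 2), n, 2)
  draws <- replicate(20000,
    spjsdm:::.update_eta(Rres, lambda, c(1, 1), st)[, 1])
  Kimp <- spatial_covariance(st[[1]])
  emp <- tcrossprod(draws) / ncol(draws)
  se <- sqrt((1 + Kimp^2) / ncol(draws))
  expect_true(all(abs(emp - Kimp) < 4.5 * se))
  # likelihood washout: enormous residual variances revert the mean to zero
  lam2 <- matrix(rnorm(2), 1, 2)
  res <- spjsdm:::.update_eta(Rres, lam2, c(1e12, 1e12), st, moments = TRUE)
  expect_lt(max(abs(res$mean)), 1e-6)
})

test_that("range sampling is exact on degenerate and symmetric grids", {
  set.seed(28)
  n <- 8; S <- random_sites(n)
  eta <- matrix(rnorm(n), n, 1)
  st <- build_spatial_structure(S, "gp", 0.3)
  # one candidate: always chosen
  expect_true(all(replicate(50,
    spjsdm:::.update_alpha(eta, list(st), 0)) == 1))
  # two identical candidates with equal prior: frequency 1/2
  k <- replicate(1e4, spjsdm:::.update_alpha(eta, list(st, st),
                                             log(c(0.5, 0.5))))
  expect_lt(abs(mean(k == 1) - 0.5), 3 * 0.5 / sqrt(1e4))
})

test_that("the range posterior concentrates at the generating value", {
  # 1-D transect, eta drawn from the exact GP; the grid-restricted posterior
  # mode should sit at or adjacent to the truth in nearly all replicates
  set.seed(29)
  n <- 200
  S <- cbind(seq(0, 1, length.out = n), 0)
  grid <- exp(seq(log(0.02), log(1), length.out = 10))
  alpha_true <- grid[5]
  sts <- lapply(grid, function(a) build_spatial_structure(S, "gp", a))
  st_true <- sts[[5]]
  hit <- 0
  for (r in 1:100) {
    eta <- spatial_prior_sample(st_true)
    lm_ <- vapply(sts, function(s) spatial_log_density(eta, s), numeric(1))
    hit <- hit + (abs(which.max(lm_) - 5) <= 1)
  }
  expect_gte(hit, 90)
})

test_that("chains are deterministic per seed and retain the scheduled draws", {
  sim <- simulate_community(n_sites = 30, n_species = 3, n_cov = 2,
                            n_factors = 1, seed = 30)
  f1 <- spjsdm(sim$train, spatial = "none", n_factors = 1, n_iter = 40,
               n_burn = 20, thin = 3, seed = 99)
  f2 <- spjsdm(sim$train, spatial = "none", n_factors = 1, n_iter = 40,
               n_burn = 20, thin = 3, seed = 99)
  f3 <- spjsdm(sim$train, spatial = "none", n_factors = 1, n_iter = 40,
               n_burn = 20, thin = 3, seed = 100)
  expect_equal(f1$config$n_draws, floor((40 - 20) / 3))
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(f1$samples$beta[1, , ], f3$samples$beta[1, , ]))
  # empty retention is allowed
  f0 <- spjsdm(sim$train, spatial = "none", n_factors = 1, n_iter = 10,
               n_burn = 10, seed = 1)
  expect_equal(f0$config$n_draws, 0)
})

test_that("a full sweep preserves support constraints", {
  set.seed(31)
  fit <- tiny_fit(seed = 31, spatial = "gpp", m = 4, n_iter = 60)
  s <- fit$samples
  expect_true(all(s$delta > 0))
  expect_true(all(s$phi > 0))
  expect_true(all(s$sigma2 == 1))          # probit scale fixed
  Y <- fit$data$Y
  for (d in seq_len(fit$config$n_draws)) {
    Z <- spjsdm:::.draw_slice(s$Z, d)
    expect_true(all(Z[Y == 1] > 0) && all(Z[Y == 0] <= 0))
  }
})

test_that("successive-conditional simulation reproduces the prior", {
  # Geweke-style check on a 10-site, 3-species, 1-factor Gaussian model:
  # alternating data simulation and full Gibbs sweeps leaves the prior
  # invariant, so chain moments must match prior moments.
  set.seed(32)
  n <- 10; ns <- 3; nf <- 1
  S <- random_sites(n)
  X <- cbind(1, rnorm(n))
  Tmat <- matrix(1, ns, 1)
  priors <- spjsdm_priors()
  Vm <- spjsdm:::.beta_prior_matrices(priors, 2)
  grid <- c(0, 0.3)
  sts <- list(build_spatial_structure(S, "iid"),
              build_spatial_structure(S, "gp", 0.3))
  upd <- list(z = FALSE, beta = TRUE, lambda = TRUE, shrinkage = TRUE,
              eta = TRUE, alpha = TRUE, sigma2 = TRUE)
  dat <- community_data(matrix(0, n, ns), X, S, family = "gaussian")
  state <- spjsdm:::.init_state(dat, nf, priors, Vm, "prior")
  n_it <- 3000
  keep <- matrix(NA_real_, n_it, 3)
  for (it in seq_len(n_it)) {
    L <- X %*% state$beta + state$eta %*% state$lambda
    Y <- L + matrix(rnorm(n * ns), n, ns) *
      rep(sqrt(state$sigma2), each = n)
    state$Z <- Y
    state <- spjsdm:::.gibbs_sweep(state, Y, X, Tmat, integer(0), 1:ns,
                                   sts, log(c(0.5, 0.5)), priors, Vm, upd)
    keep[it, ] <- c(state$beta[1, 1], state$delta[1],
                    mean(state$eta^2))
  }
  # beta_11 marginal prior: mean 0, var gamma_var + beta_var = 2
  ess_b <- effective_sample_size(keep[, 1])
  expect_lt(abs(mean(keep[, 1])), 4 * sqrt(2 / ess_b))
  expect_lt(abs(var(keep[, 1]) - 2), 4 * 2 * sqrt(2 / ess_b))
  # delta_1 prior Gamma(a1, b1): mean a1/b1
  ess_d <- effective_sample_size(keep[, 2])
  pm <- priors$a1 / priors$b1
  psd <- sqrt(priors$a1) / priors$b1
  expect_lt(abs(mean(keep[, 2]) - pm), 4 * psd / sqrt(ess_d))
  # eta second moment: prior E[eta^2] = 1 under both grid entries
  ess_e <- effective_sample_size(keep[, 3])
  expect_lt(abs(mean(keep[, 3]) - 1), 4 * sqrt(2 / n / ns / ess_e) * 3)
})
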