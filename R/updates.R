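## Full-conditional Gibbs updates.  Each function draws one block from its
## exact conditional given the rest of the state; all are internal and
## exercised directly by the conditional-correctness tests.

# --- latent probit responses -------------------------------------------------
# Z_ij ~ N(L_ij, 1) truncated to (0, Inf) if Y_ij = 1, (-Inf, 0] if Y_ij = 0,
# probit species only (Gaussian species keep Z = Y).
.update_Z <- function(Z, Y, L, probit_cols) {
  if (!length(probit_cols)) return(Z)
  mu <- L[, probit_cols, drop = FALSE]
  y1 <- Y[, probit_cols, drop = FALSE] == 1
  Z[, probit_cols] <- .rtnorm_half(as.numeric(mu), as.logical(y1))
  Z
}

# --- regression coefficients and trait coefficients --------------------------
# beta_.j | . ~ N with precision Vinv + X'X / sigma2_j and mean pulled toward
# the trait-predicted prior mean Gamma t_j; then Gamma | beta from its
# conjugate Gaussian conditional.
.update_beta_gamma <- function(Z, X, eta, lambda, traits, gamma, sigma2,
                               priors, Vmats) {
  n_c <- ncol(X); n_s <- ncol(Z); n_t <- ncol(traits)
  Vinv <- Vmats$Vinv
  XtX <- crossprod(X)
  Rres <- Z - eta %*% lambda                 # n_y x n_s
  XtR <- crossprod(X, Rres)                  # n_c x n_s
  prior_mean <- gamma %*% t(traits)          # n_c x n_s
  beta <- matrix(0, n_c, n_s)
  for (j in seq_len(n_s)) {
    Q <- Vinv + XtX / sigma2[j]
    ch <- tryCatch(chol(Q), error = function(e)
      stop("singular posterior precision in beta update (species ", j, ")"))
    lin <- Vinv %*% prior_mean[, j] + XtR[, j] / sigma2[j]
    m <- backsolve(ch, backsolve(ch, lin, transpose = TRUE))
    beta[, j] <- m + backsolve(ch, rnorm(n_c))
  }
  # Gamma | beta: vec(Gamma) Gaussian with precision G0inv + (T'T) (x) Vinv
  g0 <- rep_len(priors$gamma_mean, n_c * n_t)
  g0prec <- diag(rep_len(1 / priors$gamma_var, n_c * n_t), n_c * n_t)
  Qg <- g0prec + kronecker(crossprod(traits), Vinv)
  ling <- g0prec %*% g0 + as.numeric(Vinv %*% beta %*% traits)
  chg <- chol(Qg)
  mg <- backsolve(chg, backsolve(chg, ling, transpose = TRUE))
  gamma <- matrix(mg + backsolve(chg, rnorm(n_c * n_t)), n_c, n_t)
  list(beta = beta, gamma = gamma)
}

# --- factor loadings ---------------------------------------------------------
# lambda_.j | . ~ N with precision diag(phi_.j * tau) + (eta' eta) / sigma2_j.
.update_lambda <- function(Z, X, beta, eta, phi, tau, sigma2) {
  n_f <- ncol(eta); n_s <- ncol(Z)
  EtE <- crossprod(eta)
  Rres <- Z - X %*% beta
  EtR <- crossprod(eta, Rres)                # n_f x n_s
  lambda <- matrix(0, n_f, n_s)
  for (j in seq_len(n_s)) {
    Q <- EtE / sigma2[j]
    diag(Q) <- diag(Q) + phi[, j] * tau
    ch <- chol(Q)
    m <- backsolve(ch, backsolve(ch, EtR[, j] / sigma2[j], transpose = TRUE))
    lambda[, j] <- m + backsolve(ch, rnorm(n_f))
  }
  lambda
}

# --- multiplicative-gamma shrinkage ------------------------------------------
# phi_hj ~ Gamma((nu+1)/2, (nu + tau_h lambda_hj^2)/2); delta_l from its
# conditional with tau recomputed as cumulative products.
.update_shrinkage <- function(lambda, delta, priors) {
  n_f <- nrow(lambda); n_s <- ncol(lambda)
  tau <- cumprod(delta)
  phi <- matrix(rgamma(n_f * n_s, shape = (priors$nu + 1) / 2,
                       rate = (priors$nu + lambda^2 * tau) / 2), n_f, n_s)
  s_h <- rowSums(phi * lambda^2)             # sum_j phi_hj lambda_hj^2
  for (l in seq_len(n_f)) {
    tau <- cumprod(delta)
    tau_excl <- tau[l:n_f] / delta[l]
    shape <- (if (l == 1) priors$a1 else priors$a2) + n_s * (n_f - l + 1) / 2
    rate <- (if (l == 1) priors$b1 else priors$b2) +
      0.5 * sum(tau_excl * s_h[l:n_f])
    delta[l] <- rgamma(1, shape = shape, rate = rate)
  }
  list(phi = phi, delta = delta, tau = cumprod(delta))
}

# --- residual variances (Gaussian species only) ------------------------------
.update_sigma2 <- function(Z, L, sigma2, gauss_cols, priors) {
  for (j in gauss_cols) {
    ss <- sum((Z[, j] - L[, j])^2)
    sigma2[j] <- 1 / rgamma(1, shape = priors$sigma2_shape + nrow(Z) / 2,
                            rate = priors$sigma2_rate + ss / 2)
  }
  sigma2
}

# --- spatial range indices ---------------------------------------------------
# Per factor, sample the alpha-grid index with probability proportional to
# prior weight times the marginal Gaussian prior density of the factor.
.update_alpha <- function(eta, structures, log_weights) {
  n_f <- ncol(eta)
  idx <- integer(n_f)
  for (h in seq_len(n_f)) {
    lw <- vapply(structures, function(s) spatial_log_density(eta[, h], s),
                 numeric(1)) + log_weights
    if (!any(is.finite(lw)))
      stop("all candidate spatial-range log-marginals are non-finite")
    p <- exp(lw - max(lw, na.rm = TRUE))
    p[!is.finite(p)] <- 0
    idx[h] <- sample.int(length(p), 1, prob = p)
  }
  idx
}

# --- latent factors, all sites and factors jointly ---------------------------
# vec(eta) (factor-major) has Gaussian full conditional with precision
#   P = blockdiag_h(K_h^-1) + (Lambda Sigma^-1 Lambda') (x) I_n
# and mean P^-1 vec(R Sigma^-1 Lambda').  The solve strategy follows the
# spatial backend: dense for gp, sparse Cholesky for nngp, and a
# knot-augmented low-rank + site-block reduction for gpp (never forming a
# dense n x n matrix).  `structs` is the per-factor structure at the current
# range.  With moments = TRUE the exact conditional mean and covariance are
# also returned (dense; small problems only, used for validation).
.update_eta <- function(Rres, lambda, sigma2, structs, moments = FALSE) {
  n <- nrow(Rres); n_f <- nrow(lambda)
  Ls <- sweep(lambda, 2, sigma2, "/")
  M <- tcrossprod(Ls, lambda)                        # Lambda Sigma^-1 Lambda'
  b_mat <- Rres %*% t(Ls)                            # n x n_f
  methods_h <- vapply(structs, function(s) s$method, character(1))

  if (any(methods_h == "gp")) {
    P <- kronecker(M, diag(n))
    for (h in seq_len(n_f)) {
      blk <- (h - 1) * n + seq_len(n)
      if (methods_h[h] == "gp") {
        P[blk, blk] <- P[blk, blk] + structs[[h]]$Kinv
      } else {
        di <- cbind(blk, blk)
        P[di] <- P[di] + 1
      }
    }
    ch <- tryCatch(chol(P), error = function(e)
      stop("dense eta-precision factorization failed (gp backend)"))
    b <- as.numeric(b_mat)
    mean_vec <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
    draw <- mean_vec + backsolve(ch, rnorm(n * n_f))
    eta <- matrix(draw, n, n_f)
    if (moments)
      return(list(eta = eta, mean = matrix(mean_vec, n, n_f),
                  cov = chol2inv(ch)))
    return(eta)
  }

  if (any(methods_h == "nngp")) {
    Qs <- lapply(seq_len(n_f), function(h)
      if (methods_h[h] == "nngp") structs[[h]]$Q else Matrix::Diagonal(n))
    P <- Matrix::forceSymmetric(
      Matrix::bdiag(Qs) + Matrix::kronecker(Matrix::Matrix(M),
                                            Matrix::Diagonal(n)))
    ch <- tryCatch(Matrix::Cholesky(P, LDL = FALSE, perm = TRUE),
                   error = function(e)
      stop("sparse eta-precision factorization failed (nngp backend, alpha = ",
           paste(vapply(structs, `[[`, numeric(1), "alpha"), collapse = ", "),
           ")"))
    b <- as.numeric(b_mat)
    mean_vec <- as.numeric(Matrix::solve(ch, b, system = "A"))
    u <- Matrix::solve(ch, rnorm(n * n_f), system = "Lt")
    dev <- as.numeric(Matrix::solve(ch, u, system = "Pt"))
    eta <- matrix(mean_vec + dev, n, n_f)
    if (moments)
      return(list(eta = eta, mean = matrix(mean_vec, n, n_f),
                  cov = as.matrix(Matrix::solve(P))))
    return(eta)
  }

  # gpp and/or iid factors: knot augmentation.  Writing the gpp prior as
  # eta_h = U_h v_h + sqrt(c_h) z with v_h ~ N(0, I_m), the pair (eta, v) has
  # a Gaussian full conditional whose eta-marginal is exactly N(P^-1 b, P^-1);
  # v is sampled from its marginal (an (nf m*)-dense system) and eta | v
  # factorizes over sites into nf x nf blocks.
  gpp_h <- which(methods_h == "gpp")
  g <- matrix(1, n, n_f)
  for (h in gpp_h) g[, h] <- 1 / structs[[h]]$c

  H <- array(0, c(n_f, n_f, n))           # site-block inverses (M + diag(g_i))^-1
  cholH <- array(0, c(n_f, n_f, n))
  u <- matrix(0, n, n_f)                  # Pd^-1 b
  for (i in seq_len(n)) {
    Qi <- M
    diag(Qi) <- diag(Qi) + g[i, ]
    Hi <- chol2inv(chol(Qi))
    H[, , i] <- Hi
    cholH[, , i] <- chol(Hi)
    u[i, ] <- Hi %*% b_mat[i, ]
  }

  if (length(gpp_h)) {
    Us <- lapply(gpp_h, function(h) structs[[h]]$U * g[, h])   # C^-1 U per factor
    mlist <- vapply(Us, ncol, integer(1))
    offs <- c(0, cumsum(mlist))
    nv <- sum(mlist)
    Sv <- matrix(0, nv, nv)
    rhs <- numeric(nv)
    for (a in seq_along(gpp_h)) {
      ia <- offs[a] + seq_len(mlist[a])
      ha <- gpp_h[a]
      Sv[ia, ia] <- crossprod(structs[[ha]]$Wchol)             # I + U'C^-1 U
      rhs[ia] <- crossprod(Us[[a]], u[, ha])
      for (bb in seq_along(gpp_h)) {
        ib <- offs[bb] + seq_len(mlist[bb])
        hb <- gpp_h[bb]
        Sv[ia, ib] <- Sv[ia, ib] -
          crossprod(Us[[a]] * H[ha, hb, ], Us[[bb]])
      }
    }
    chS <- tryCatch(chol(Sv), error = function(e)
      stop("knot-system factorization failed (gpp backend)"))
    v_mean <- backsolve(chS, backsolve(chS, rhs, transpose = TRUE))
    v <- v_mean + backsolve(chS, rnorm(nv))
    Bv <- matrix(0, n, n_f)
    for (a in seq_along(gpp_h))
      Bv[, gpp_h[a]] <- (structs[[gpp_h[a]]]$U %*%
                           v[offs[a] + seq_len(mlist[a])]) * g[, gpp_h[a]]
  } else {
    Bv <- matrix(0, n, n_f)
    v_mean <- numeric(0)
  }

  eta <- matrix(0, n, n_f)
  z <- matrix(rnorm(n * n_f), n_f, n)
  for (i in seq_len(n)) {
    mi <- H[, , i] %*% (b_mat[i, ] + Bv[i, ])
    eta[i, ] <- mi + crossprod(matrix(cholH[, , i], n_f, n_f), z[, i])
  }

  if (moments) {
    # exact conditional moments from the same factorized pieces
    N <- n * n_f
    Pdinv <- matrix(0, N, N)
    for (i in seq_len(n)) {
      rows <- (seq_len(n_f) - 1) * n + i
      Pdinv[rows, rows] <- H[, , i]
    }
    if (length(gpp_h)) {
      Bd <- matrix(0, N, length(rhs))
      for (a in seq_along(gpp_h)) {
        ha <- gpp_h[a]
        Bd[(ha - 1) * n + seq_len(n), offs[a] + seq_len(mlist[a])] <- Us[[a]]
      }
      PB <- Pdinv %*% Bd
      Svinv <- chol2inv(chol(Sv))
      cov <- Pdinv + PB %*% Svinv %*% t(PB)
      mean_vec <- Pdinv %*% as.numeric(b_mat) + PB %*% (Svinv %*% rhs)
    } else {
      cov <- Pdinv
      mean_vec <- Pdinv %*% as.numeric(b_mat)
    }
    return(list(eta = eta, mean = matrix(mean_vec, n, n_f), cov = cov))
  }
  eta
}
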