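#' Latent linear predictor
#'
#' Evaluates the site-by-species latent predictor
#' \eqn{L = X\beta + \eta\Lambda}: a linear regression on site covariates plus
#' the latent-factor representation of residual species dependence.
#'
#' @param X site-by-covariate design matrix.
#' @param beta covariate-by-species coefficient matrix.
#' @param eta site-by-factor latent factor matrix.
#' @param lambda factor-by-species loading matrix.
#' @return site-by-species matrix `L`.
#' @examples
#' linear_predictor(matrix(1), matrix(2), matrix(3), matrix(0.5))  # 3.5
#' @export
linear_predictor <- function(X, beta, eta, lambda) {
  X <- as.matrix(X); beta <- as.matrix(beta)
  eta <- as.matrix(eta); lambda <- as.matrix(lambda)
  if (ncol(X) != nrow(beta))
    stop("ncol(X) = ", ncol(X), " but nrow(beta) = ", nrow(beta))
  if (ncol(eta) != nrow(lambda))
    stop("ncol(eta) = ", ncol(eta), " but nrow(lambda) = ", nrow(lambda))
  if (nrow(X) != nrow(eta))
    stop("`X` and `eta` must have the same number of rows")
  if (ncol(beta) != ncol(lambda))
    stop("`beta` and `lambda` must have the same number of species columns")
  X %*% beta + eta %*% lambda
}

#' Occurrence probability under the probit link
#'
#' Maps latent values to presence probabilities via the standard-normal CDF,
#' \eqn{p = \Phi(L)}.
#'
#' @param L numeric vector or matrix of latent values.
#' @return probabilities in `[0, 1]`, same shape as `L`.
#' @examples
#' occurrence_probability(0)         # 0.5
#' occurrence_probability(1.959964)  # 0.975
#' @export
occurrence_probability <- function(L) {
  if (!all(is.finite(L) | is.infinite(L))) stop("`L` must not contain NA")
  pnorm(L)
}

#' Species-to-species association matrix from factor loadings
#'
#' The low-rank residual covariance among species implied by the loadings is
#' \eqn{\Omega = \Lambda^T \Lambda}; its correlation scaling
#' \eqn{\Omega^*_{jk} = \Omega_{jk} / \sqrt{\Omega_{jj}\Omega_{kk}}} is the
#' species-association matrix, whose positive (negative) entries indicate
#' pairs co-occurring more (less) often than the covariates explain.
#'
#' @param lambda factor-by-species loading matrix.
#' @return list with `omega` (covariance, species-by-species, positive
#'   semidefinite) and `omega_cor` (correlation scaling, unit diagonal).
#'   Species whose loading column is entirely zero have undefined correlation
#'   entries, which are returned as `NA` with a warning rather than silent
#'   `NaN`.
#' @examples
#' association_matrix(matrix(c(1, -1), 1))$omega_cor  # perfect negative pair
#' @export
association_matrix <- function(lambda) {
  lambda <- as.matrix(lambda)
  omega <- crossprod(lambda)            # Lambda' Lambda, n_s x n_s
  d <- diag(omega)
  bad <- d <= 0
  s <- sqrt(ifelse(bad, NA_real_, d))
  omega_cor <- omega / outer(s, s)
  diag(omega_cor) <- ifelse(bad, NA_real_, 1)
  if (any(bad))
    warning("species with all-zero loadings: correlation undefined (NA) for ",
            sum(bad), " species")
  dn <- colnames(lambda)
  if (!is.null(dn))
    dimnames(omega) <- dimnames(omega_cor) <- list(dn, dn)
  list(omega = omega, omega_cor = omega_cor)
}

#' Prior hyperparameters for a spatial JSDM
#'
#' Collects all prior hyperparameters.  Loadings carry the
#' multiplicative-gamma (increasing-shrinkage) prior: local precisions
#' `phi_hj ~ Gamma(nu/2, nu/2)` and global column precisions
#' `tau_h = prod(delta_1..delta_h)` with `delta_1 ~ Gamma(a1, b1)`,
#' `delta_l ~ Gamma(a2, b2)` for `l > 1`.  With `a2 > 1` the expected
#' increments exceed 1 so higher factors are shrunk progressively harder.
#' Regression rows have Gaussian priors centred on the trait regression,
#' `beta_j ~ N(Gamma' t_j, V)`, and `vec(Gamma)` has an independent Gaussian
#' prior.  Gaussian species have inverse-gamma residual-variance priors;
#' probit species have `sigma2` fixed at 1 for identifiability of the probit
#' scale.
#'
#' @param nu,a1,b1,a2,b2 multiplicative-gamma shrinkage hyperparameters.
#' @param gamma_mean,gamma_var prior mean and (scalar or vector) variance for
#'   the entries of the trait-coefficient matrix Gamma.
#' @param beta_var prior covariance `V` of a species' coefficient row about
#'   its trait-predicted mean: a scalar (multiple of the identity), vector
#'   (diagonal) or full matrix.
#' @param sigma2_shape,sigma2_rate inverse-gamma prior for Gaussian residual
#'   variances.
#' @return object of class `"spjsdm_priors"`.
#' @export
spjsdm_priors <- function(nu = 3, a1 = 5, b1 = 1, a2 = 5, b2 = 1,
                          gamma_mean = 0, gamma_var = 1, beta_var = 1,
                          sigma2_shape = 1, sigma2_rate = 1) {
  stopifnot(nu > 0, a1 > 0, b1 > 0, a2 > 0, b2 > 0,
            all(gamma_var > 0), sigma2_shape > 0, sigma2_rate > 0)
  if (is.matrix(beta_var)) {
    if (!isSymmetric(beta_var) || any(eigen(beta_var, TRUE, TRUE)$values <= 0))
      stop("`beta_var` matrix must be symmetric positive-definite")
  } else if (any(beta_var <= 0)) stop("`beta_var` must be positive")
  structure(list(nu = nu, a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 gamma_mean = gamma_mean, gamma_var = gamma_var,
                 beta_var = beta_var,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate),
            class = "spjsdm_priors")
}

# Expand beta_var prior to an n_c x n_c covariance and its inverse.
.beta_prior_matrices <- function(priors, n_c) {
  V <- priors$beta_var
  if (is.matrix(V)) {
    if (nrow(V) != n_c) stop("`beta_var` must be ", n_c, " x ", n_c)
  } else {
    V <- diag(rep_len(V, n_c), n_c)
  }
  list(V = V, Vinv = chol2inv(chol(V)))
}
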