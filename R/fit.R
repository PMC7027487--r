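#' Fit a spatial joint species distribution model
#'
#' Draws from the posterior of a latent-factor JSDM by a full-conditional
#' block Gibbs sampler.  The latent predictor is `L = X beta + eta lambda`;
#' probit species are handled by truncated-normal data augmentation, Gaussian
#' species enter the identity-link likelihood directly.  Each factor's spatial
#' prior is governed by a range parameter `alpha` sampled over a discrete
#' grid (`alpha = 0` meaning an unstructured, spatially independent factor),
#' with the covariance represented exactly (`"gp"`), by a knot-based
#' predictive process (`"gpp"`), or by a nearest-neighbour GP (`"nngp"`).
#'
#' One sweep updates, in order: the augmented responses `Z`, the regression
#' and trait coefficients (`beta`, `Gamma`), the loadings `lambda`, the
#' multiplicative-gamma shrinkage variables, all latent factors `eta` jointly,
#' the per-factor ranges `alpha`, and Gaussian residual variances `sigma2`.
#' Covariance structures for every candidate range are factorized once before
#' sampling.  Runs with the same `seed` are exactly reproducible.
#'
#' @param Y site-by-species response matrix, or a [community_data()] object
#'   (in which case `X`, `coords`, `traits`, `family` are taken from it).
#' @param X,coords,traits,family see [community_data()].
#' @param n_factors number of latent factors (fixed truncation, >= 1).
#' @param spatial spatial representation of the factors: `"nngp"`, `"gpp"`,
#'   `"gp"` or `"none"`.
#' @param m number of nearest neighbours (`"nngp"`) or target knot count
#'   (`"gpp"`); ignored otherwise.
#' @param alpha_grid candidate spatial ranges (distance units).  Default: 0
#'   (nonspatial) plus 20 log-spaced values from 0.01 to 1 times the maximum
#'   inter-site distance.
#' @param alpha_weights prior weights over `alpha_grid` (default uniform).
#' @param priors a [spjsdm_priors()] object.
#' @param n_iter,n_burn,thin iteration schedule; `floor((n_iter - n_burn) /
#'   thin)` draws are retained.
#' @param seed integer seed for exact reproducibility (optional).
#' @param init `"default"` (neutral deterministic-mean start) or `"prior"`
#'   (parameters drawn from their priors, for multi-chain convergence checks).
#' @param store_latent keep per-draw `eta`, `Z` and `phi` (default `TRUE`;
#'   turn off to save memory on large problems — prediction at new sites
#'   requires `eta`).
#' @param verbose print progress every 10% of iterations.
#' @param updates named list of logical flags (`z`, `beta`, `lambda`,
#'   `shrinkage`, `eta`, `alpha`, `sigma2`) enabling individual Gibbs blocks;
#'   intended for conditional-correctness testing.
#' @return object of class `"spjsdm"` with components `samples` (arrays of
#'   retained draws, draw index first), `data`, `spec`, `priors`, `config`
#'   and `runtime`.
#' @examples
#' sim <- simulate_community(n_sites = 72, n_species = 4, seed = 1)
#' fit <- spjsdm(sim$train, spatial = "nngp", m = 5,
#'               n_iter = 200, n_burn = 100, seed = 1)
#' fit
#' @export
spjsdm <- function(Y, X = NULL, coords = NULL, traits = NULL,
                   family = "probit", n_factors = 2,
                   spatial = c("nngp", "gpp", "gp", "none"), m = 10,
                   alpha_grid = NULL, alpha_weights = NULL,
                   priors = spjsdm_priors(),
                   n_iter = 1000, n_burn = floor(n_iter / 2), thin = 1,
                   seed = NULL, init = c("default", "prior"),
                   store_latent = TRUE, verbose = FALSE, updates = list()) {
  cl <- match.call()
  spatial <- match.arg(spatial)
  init <- match.arg(init)
  dat <- if (inherits(Y, "community_data")) Y else
    community_data(Y, X, coords, traits, family)
  if (n_factors < 1) stop("`n_factors` must be >= 1")
  if (spatial %in% c("gpp", "nngp") && m < 1)
    stop("`m` must be >= 1 for spatial = \"", spatial, "\"")
  if (!(n_iter >= n_burn && n_burn >= 0)) stop("need n_iter >= n_burn >= 0")
  if (thin < 1) stop("`thin` must be >= 1")

  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid(dat$coords)
  if (any(alpha_grid < 0)) stop("`alpha_grid` values must be >= 0")
  if (is.null(alpha_weights))
    alpha_weights <- rep(1 / length(alpha_grid), length(alpha_grid))
  if (length(alpha_weights) != length(alpha_grid) ||
      abs(sum(alpha_weights) - 1) > 1e-8)
    stop("`alpha_weights` must match `alpha_grid` and sum to 1")

  upd <- modifyList(list(z = TRUE, beta = TRUE, lambda = TRUE,
                         shrinkage = TRUE, eta = TRUE, alpha = TRUE,
                         sigma2 = TRUE), updates)

  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]

  built <- .build_structures(dat$coords, if (spatial == "none") "none" else
                               spatial, alpha_grid, m)
  structures <- built$structures
  log_w <- log(alpha_weights)

  n <- dat$n_sites; n_s <- dat$n_species; n_c <- dat$n_cov
  n_t <- dat$n_traits; n_f <- n_factors
  Xd <- dat$X; Yd <- dat$Y; Td <- dat$traits
  probit_cols <- which(dat$family == "probit")
  gauss_cols <- which(dat$family == "gaussian")
  Vmats <- .beta_prior_matrices(priors, n_c)

  # initial state
  state <- .init_state(dat, n_f, priors, Vmats, init)

  n_draws <- as.integer((n_iter - n_burn) %/% thin)
  samples <- list(
    beta = array(NA_real_, c(n_draws, n_c, n_s)),
    gamma = array(NA_real_, c(n_draws, n_c, n_t)),
    lambda = array(NA_real_, c(n_draws, n_f, n_s)),
    alpha_index = matrix(NA_integer_, n_draws, n_f),
    sigma2 = matrix(NA_real_, n_draws, n_s),
    delta = matrix(NA_real_, n_draws, n_f))
  if (store_latent) {
    samples$eta <- array(NA_real_, c(n_draws, n, n_f))
    samples$phi <- array(NA_real_, c(n_draws, n_f, n_s))
    samples$Z <- array(NA_real_, c(n_draws, n, n_s))
  }

  d <- 0L
  for (it in seq_len(n_iter)) {
    res <- tryCatch(
      .gibbs_sweep(state, Yd, Xd, Td, probit_cols, gauss_cols, structures,
                   log_w, priors, Vmats, upd),
      error = function(e)
        stop("Gibbs update failed at iteration ", it, ": ",
             conditionMessage(e)))
    state <- res
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      d <- d + 1L
      samples$beta[d, , ] <- state$beta
      samples$gamma[d, , ] <- state$gamma
      samples$lambda[d, , ] <- state$lambda
      samples$alpha_index[d, ] <- state$alpha_index
      samples$sigma2[d, ] <- state$sigma2
      samples$delta[d, ] <- state$delta
      if (store_latent) {
        samples$eta[d, , ] <- state$eta
        samples$phi[d, , ] <- state$phi
        samples$Z[d, , ] <- state$Z
      }
    }
    if (verbose && it %% max(1, n_iter %/% 10) == 0)
      message("iteration ", it, "/", n_iter, " (", d, " draws retained)")
  }

  structure(list(
    call = cl, data = dat,
    spec = list(n_factors = n_f, spatial = spatial, m = m,
                alpha_grid = alpha_grid, alpha_weights = alpha_weights,
                knots = if (spatial == "gpp") built$aux else NULL),
    priors = priors,
    config = list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                  seed = seed, n_draws = n_draws),
    samples = samples,
    runtime = proc.time()[["elapsed"]] - t0), class = "spjsdm")
}

#' Default candidate grid of spatial ranges
#'
#' 0 (a spatially unstructured factor) plus 20 log-spaced values between 0.01
#' and 1 times the maximum inter-site distance.
#'
#' @param coords site coordinates.
#' @param n_nonzero number of nonzero candidates.
#' @return numeric vector of candidate ranges.
#' @export
default_alpha_grid <- function(coords, n_nonzero = 20) {
  coords <- as.matrix(coords)
  d_max <- if (nrow(coords) <= 3000) max(.dist_self(coords)) else
    sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  if (d_max <= 0) stop("sites are coincident; no spatial scale available")
  c(0, exp(seq(log(0.01 * d_max), log(d_max), length.out = n_nonzero)))
}

.init_state <- function(dat, n_f, priors, Vmats, init) {
  n <- dat$n_sites; n_s <- dat$n_species
  n_c <- dat$n_cov; n_t <- dat$n_traits
  if (init == "prior") {
    gamma <- matrix(rnorm(n_c * n_t, priors$gamma_mean,
                          sqrt(priors$gamma_var)), n_c, n_t)
    Rv <- chol(Vmats$V)
    beta <- gamma %*% t(dat$traits) +
      crossprod(Rv, matrix(rnorm(n_c * n_s), n_c, n_s))
    delta <- c(rgamma(1, priors$a1, priors$b1),
               rgamma(max(0, n_f - 1), priors$a2, priors$b2))
    phi <- matrix(rgamma(n_f * n_s, priors$nu / 2, priors$nu / 2), n_f, n_s)
    lambda <- matrix(rnorm(n_f * n_s), n_f, n_s) /
      sqrt(phi * cumprod(delta))
    eta <- matrix(rnorm(n * n_f), n, n_f)
  } else {
    gamma <- matrix(0, n_c, n_t)
    beta <- matrix(0, n_c, n_s)
    delta <- c(priors$a1 / priors$b1, rep(priors$a2 / priors$b2,
                                          max(0, n_f - 1)))
    phi <- matrix(1, n_f, n_s)
    lambda <- matrix(0.05 * rnorm(n_f * n_s), n_f, n_s)
    eta <- matrix(rnorm(n * n_f), n, n_f)
  }
  Z <- dat$Y
  pc <- dat$family == "probit"
  if (any(pc)) {
    hm <- sqrt(2 / pi)                    # half-normal mean start
    Z[, pc] <- ifelse(dat$Y[, pc] == 1, hm, -hm)
  }
  list(Z = Z, beta = beta, gamma = gamma, lambda = lambda, eta = eta,
       alpha_index = rep(1L, n_f), phi = phi, delta = delta,
       tau = cumprod(delta), sigma2 = rep(1, n_s))
}

.gibbs_sweep <- function(state, Y, X, Tmat, probit_cols, gauss_cols,
                         structures, log_w, priors, Vmats, upd) {
  if (upd$z) {
    L <- X %*% state$beta + state$eta %*% state$lambda
    state$Z <- .update_Z(state$Z, Y, L, probit_cols)
  }
  if (upd$beta) {
    bg <- .update_beta_gamma(state$Z, X, state$eta, state$lambda, Tmat,
                             state$gamma, state$sigma2, priors, Vmats)
    state$beta <- bg$beta; state$gamma <- bg$gamma
  }
  if (upd$lambda)
    state$lambda <- .update_lambda(state$Z, X, state$beta, state$eta,
                                   state$phi, state$tau, state$sigma2)
  if (upd$shrinkage) {
    sh <- .update_shrinkage(state$lambda, state$delta, priors)
    state$phi <- sh$phi; state$delta <- sh$delta; state$tau <- sh$tau
  }
  if (upd$eta) {
    Rres <- state$Z - X %*% state$beta
    structs <- structures[state$alpha_index]
    state$eta <- .update_eta(Rres, state$lambda, state$sigma2, structs)
  }
  if (upd$alpha)
    state$alpha_index <- .update_alpha(state$eta, structures, log_w)
  if (upd$sigma2 && length(gauss_cols)) {
    L <- X %*% state$beta + state$eta %*% state$lambda
    state$sigma2 <- .update_sigma2(state$Z, L, state$sigma2, gauss_cols,
                                   priors)
  }
  state
}

# dimension-safe extraction of draw d from a (draws x A x B) array
.draw_slice <- function(a, d) {
  out <- array(a[d, , , drop = FALSE], dim(a)[-1])
  out
}

#' @export
print.spjsdm <- function(x, ...) {
  cat("Spatial JSDM fit (", x$spec$spatial, " latent factors)\n", sep = "")
  cat("  sites:", x$data$n_sites, " species:", x$data$n_species,
      " covariates:", x$data$n_cov, " factors:", x$spec$n_factors, "\n")
  if (x$spec$spatial %in% c("gpp", "nngp"))
    cat("  m =", if (x$spec$spatial == "gpp")
      x$spec$knots$m_star else x$spec$m,
      if (x$spec$spatial == "gpp") "knots" else "neighbours", "\n")
  cat("  chain:", x$config$n_iter, "iterations,", x$config$n_burn,
      "burn-in, thin", x$config$thin, "->", x$config$n_draws,
      "retained draws\n")
  cat("  runtime:", round(x$runtime, 1), "s\n")
  invisible(x)
}

#' @export
coef.spjsdm <- function(object, ...) {
  b <- apply(object$samples$beta, c(2, 3), mean)
  dimnames(b) <- list(colnames(object$data$X), object$data$species_names)
  b
}

#' @export
fitted.spjsdm <- function(object, ...) {
  if (is.null(object$samples$eta))
    stop("fit was run with store_latent = FALSE; refit to obtain fitted values")
  s <- object$samples
  nd <- object$config$n_draws
  out <- 0
  probit <- object$data$family == "probit"
  for (d in seq_len(nd)) {
    L <- linear_predictor(object$data$X, .draw_slice(s$beta, d),
                          .draw_slice(s$eta, d), .draw_slice(s$lambda, d))
    L[, probit] <- pnorm(L[, probit, drop = FALSE])
    out <- out + L / nd
  }
  dimnames(out) <- list(object$data$site_ids, object$data$species_names)
  out
}

#' @export
residuals.spjsdm <- function(object, ...) object$data$Y - fitted(object)

#' @export
summary.spjsdm <- function(object, level = 0.95, ...) {
  s <- object$samples
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  beta_mean <- apply(s$beta, c(2, 3), mean)
  beta_lo <- apply(s$beta, c(2, 3), quantile, probs = pr[1])
  beta_hi <- apply(s$beta, c(2, 3), quantile, probs = pr[2])
  dn <- list(colnames(object$data$X), object$data$species_names)
  dimnames(beta_mean) <- dimnames(beta_lo) <- dimnames(beta_hi) <- dn
  alpha_tab <- apply(s$alpha_index, 2, function(ix)
    tabulate(ix, nbins = length(object$spec$alpha_grid)) / length(ix))
  rownames(alpha_tab) <- signif(object$spec$alpha_grid, 3)
  out <- list(fit = object, level = level, beta_mean = beta_mean,
              beta_lower = beta_lo, beta_upper = beta_hi,
              alpha_posterior = alpha_tab,
              sigma2_mean = colMeans(s$sigma2))
  class(out) <- "summary.spjsdm"
  out
}

#' @export
print.summary.spjsdm <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior mean regression coefficients (beta):\n")
  print(round(x$beta_mean, 3))
  cat("\nPosterior distribution of spatial range (columns = factors):\n")
  ap <- x$alpha_posterior
  print(round(ap[rowSums(ap) > 0, , drop = FALSE], 3))
  invisible(x)
}

#' @export
plot.spjsdm <- function(x, type = c("trace", "associations"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    s <- x$samples
    graphics::plot(s$beta[, 1, 1], type = "l", xlab = "draw",
                   ylab = expression(beta[11]), main = "intercept, species 1")
    graphics::plot(s$lambda[, 1, 1], type = "l", xlab = "draw",
                   ylab = expression(lambda[11]), main = "loading, factor 1")
    graphics::matplot(matrix(x$spec$alpha_grid[s$alpha_index],
                             nrow(s$alpha_index)), type = "s",
                      xlab = "draw", ylab = expression(alpha),
                      main = "spatial range by factor", lty = 1)
    graphics::plot(s$sigma2[, 1], type = "l", xlab = "draw",
                   ylab = expression(sigma[1]^2), main = "residual variance")
  } else {
    as <- association_support(x)
    om <- as$mean
    om[!as$support] <- NA
    n_s <- ncol(om)
    graphics::image(seq_len(n_s), seq_len(n_s), om[, n_s:1],
                    zlim = c(-1, 1),
                    col = grDevices::hcl.colors(41, "Blue-Red 3"),
                    xlab = "species", ylab = "species",
                    main = "credible associations (posterior mean)")
  }
  invisible(x)
}

#' Simulate responses from the posterior predictive at the training sites
#'
#' @param object a fitted [spjsdm()] model.
#' @param nsim number of replicate response matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` site-by-species matrices.
#' @export
simulate.spjsdm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$samples
  if (is.null(s$eta)) stop("requires a fit with store_latent = TRUE")
  nd <- object$config$n_draws
  probit <- object$data$family == "probit"
  n <- object$data$n_sites; n_s <- object$data$n_species
  lapply(seq_len(nsim), function(k) {
    d <- sample.int(nd, 1)
    L <- linear_predictor(object$data$X, .draw_slice(s$beta, d),
                          .draw_slice(s$eta, d), .draw_slice(s$lambda, d))
    out <- L
    out[, probit] <- rbinom(n * sum(probit), 1,
                            pnorm(L[, probit, drop = FALSE]))
    if (any(!probit))
      out[, !probit] <- L[, !probit, drop = FALSE] +
        rnorm(n * sum(!probit)) *
          rep(sqrt(s$sigma2[d, !probit]), each = n)
    out
  })
}
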