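#' Covariate design matrix for synthetic communities
#'
#' Column 1 is the intercept; the remaining columns are independent standard
#' normal draws.  With `quadratic = TRUE` each non-intercept column is paired
#' with its squared (then re-centred/scaled) copy, mimicking designs where
#' responses may peak at intermediate covariate values.
#'
#' @param n_sites number of rows.
#' @param n_cov number of columns before squaring (including the intercept).
#' @param quadratic add squared copies of the non-intercept columns.
#' @return design matrix with `n_cov` columns (`2 * n_cov - 1` when
#'   `quadratic`).
#' @examples
#' dim(make_covariates(10, 3, quadratic = TRUE))  # 10 x 5
#' @export
make_covariates <- function(n_sites, n_cov, quadratic = FALSE) {
  if (n_cov < 1) stop("`n_cov` must be >= 1")
  X <- matrix(1, n_sites, 1, dimnames = list(NULL, "(Intercept)"))
  if (n_cov > 1) {
    Xl <- matrix(rnorm(n_sites * (n_cov - 1)), n_sites)
    colnames(Xl) <- paste0("x", seq_len(n_cov - 1))
    X <- cbind(X, Xl)
    if (quadratic) {
      Xq <- scale(Xl^2)
      colnames(Xq) <- paste0("x", seq_len(n_cov - 1), "_sq")
      X <- cbind(X, Xq)
    }
  }
  X
}

#' Simulate a spatially structured community with known truth
#'
#' Generates data from exactly the model the sampler targets: coordinates are
#' drawn under the requested scheme; each latent factor is drawn from the
#' exact dense GP with exponential covariance `exp(-d/alpha_h)` jointly over
#' all sites; the latent predictor `L = X beta + eta lambda` is observed as
#' `Y ~ Bernoulli(pnorm(L))` (probit) or `Y ~ N(L, sigma^2)` (gaussian).
#' Sites are split uniformly at random into training and validation sets.
#'
#' @param n_sites total number of sites (training + validation); dense GP
#'   simulation is refused above 20000 sites (simulate in blocks instead).
#' @param n_species,n_cov,n_factors community dimensions (`n_cov` counts the
#'   intercept).
#' @param coords_scheme `"uniform"` (unit square), `"clustered"` (Gaussian
#'   clusters in the unit square) or `"transect"` (equispaced on a 1-D line,
#'   second coordinate 0).
#' @param alpha true spatial range per factor (recycled); units of the
#'   coordinate extent (the unit square/segment).
#' @param beta true covariate-by-species coefficient matrix, or `NULL` to
#'   draw entries as standard normal.
#' @param lambda true factor-by-species loading matrix, or `NULL` to draw
#'   row-scaled normal loadings (scale `1/h` for factor `h`, mirroring
#'   increasing shrinkage).
#' @param family `"probit"` or `"gaussian"` (single value for all species).
#' @param sigma residual standard deviation for Gaussian responses.
#' @param prop_validation fraction of sites held out for validation.
#' @param quadratic passed to [make_covariates()].
#' @param seed optional seed; identical seeds give identical communities.
#' @return list with `train` and `validation` ([community_data()] objects)
#'   and `truth` (list of every generating parameter, including the latent
#'   factors and the train/validation index split).
#' @examples
#' sim <- simulate_community(n_sites = 60, n_species = 5, seed = 42)
#' sim$train
#' @export
simulate_community <- function(n_sites = 480, n_species = 8, n_cov = 3,
                               n_factors = 2,
                               coords_scheme = c("uniform", "clustered",
                                                 "transect"),
                               alpha = 0.2, beta = NULL, lambda = NULL,
                               family = c("probit", "gaussian"), sigma = 1,
                               prop_validation = 1 / 6, quadratic = FALSE,
                               seed = NULL) {
  coords_scheme <- match.arg(coords_scheme)
  family <- match.arg(family)
  stopifnot(n_sites >= 2, n_species >= 1, n_cov >= 1, n_factors >= 1,
            prop_validation > 0, prop_validation < 1, all(alpha > 0))
  if (n_sites > 20000)
    stop("n_sites > 20000: dense GP simulation would need too much memory; ",
         "simulate in blocks of sites instead")
  if (!is.null(seed)) set.seed(seed)

  coords <- switch(coords_scheme,
    uniform = cbind(runif(n_sites), runif(n_sites)),
    clustered = {
      k <- max(3, round(n_sites / 60))
      centers <- cbind(runif(k), runif(k))
      id <- sample.int(k, n_sites, replace = TRUE)
      pmin(pmax(centers[id, ] + matrix(rnorm(2 * n_sites, sd = 0.04),
                                       n_sites), 0), 1)
    },
    transect = cbind(seq(0, 1, length.out = n_sites), 0))

  X <- make_covariates(n_sites, n_cov, quadratic = quadratic)
  n_c <- ncol(X)
  if (is.null(beta)) beta <- matrix(rnorm(n_c * n_species), n_c, n_species)
  if (is.null(lambda))
    lambda <- matrix(rnorm(n_factors * n_species), n_factors, n_species) /
      seq_len(n_factors)
  beta <- as.matrix(beta); lambda <- as.matrix(lambda)
  if (nrow(beta) != n_c || ncol(beta) != n_species)
    stop("`beta` must be ", n_c, " x ", n_species)
  if (nrow(lambda) != n_factors || ncol(lambda) != n_species)
    stop("`lambda` must be ", n_factors, " x ", n_species)
  alpha <- rep_len(alpha, n_factors)

  eta <- matrix(0, n_sites, n_factors)
  for (h in seq_len(n_factors)) {
    st <- build_spatial_structure(coords, "gp", alpha[h])
    eta[, h] <- spatial_prior_sample(st)
  }

  L <- linear_predictor(X, beta, eta, lambda)
  Y <- if (family == "probit") {
    matrix(rbinom(length(L), 1, pnorm(L)), nrow(L))
  } else {
    L + matrix(rnorm(length(L), sd = sigma), nrow(L))
  }
  colnames(Y) <- paste0("sp", seq_len(n_species))

  n_val <- max(1, round(prop_validation * n_sites))
  val_idx <- sort(sample.int(n_sites, n_val))
  tr_idx <- setdiff(seq_len(n_sites), val_idx)

  subset_cd <- function(idx)
    community_data(Y[idx, , drop = FALSE], X[idx, , drop = FALSE],
                   coords[idx, , drop = FALSE], family = family)
  list(train = subset_cd(tr_idx),
       validation = subset_cd(val_idx),
       truth = list(beta = beta, lambda = lambda, eta = eta, alpha = alpha,
                    coords = coords, X = X, sigma = sigma,
                    train_idx = tr_idx, validation_idx = val_idx,
                    family = family, coords_scheme = coords_scheme))
}
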