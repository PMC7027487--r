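## Posterior prediction at training and new sites.

# Per-draw latent factors at new sites.  For each factor and each retained
# draw the new-site factor value is *sampled* from its conditional
# distribution given that draw (not set to the conditional mean), so that
# spatial uncertainty is marginalized into downstream probabilities:
#   gp   - joint conditional Gaussian given the training-site factor values
#   gpp  - knot values implied by the draw, plus the corrected residual
#          variance, so the predictive marginal prior variance is 1
#   nngp - conditional on the m nearest training sites
#   iid (alpha = 0 draws) - independent standard normal
# Returns an (n_draws x n_new x n_factors) array.  With sample = FALSE the
# conditional mean is returned instead of a draw (iid factors then give 0).
.predict_eta <- function(object, newcoords, sample = TRUE) {
  newcoords <- as.matrix(newcoords)
  if (!all(is.finite(newcoords))) stop("new-site coordinates must be finite")
  s <- object$samples
  if (is.null(s$eta))
    stop("prediction at new sites requires a fit with store_latent = TRUE")
  nd <- object$config$n_draws
  n0 <- nrow(newcoords); n_f <- object$spec$n_factors
  method <- object$spec$spatial
  coords <- object$data$coords
  grid <- object$spec$alpha_grid
  m <- object$spec$m
  eta0 <- if (sample) array(rnorm(nd * n0 * n_f), c(nd, n0, n_f)) else
    array(0, c(nd, n0, n_f))                           # iid fallback

  if (method == "none") return(eta0)

  nn_idx <- NULL
  if (method == "nngp") {
    Dx <- .dist_cross(newcoords, coords)
    nn_idx <- t(apply(Dx, 1, function(d)
      sort(order(d, seq_along(d))[seq_len(min(m, ncol(Dx)))])))
  }

  for (h in seq_len(n_f)) {
    for (ai in unique(s$alpha_index[, h])) {
      draws <- which(s$alpha_index[, h] == ai)
      alpha <- grid[ai]
      if (alpha == 0) next                     # keep iid standard normals
      etas <- matrix(s$eta[draws, , h], nrow = length(draws))  # nd_a x n
      if (method == "gp") {
        st <- build_spatial_structure(coords, "gp", alpha)
        Kc <- exp_cov(.dist_cross(newcoords, coords), alpha)
        Wt <- Kc %*% st$Kinv                   # kriging weights, n0 x n
        C0 <- exp_cov(.dist_self(newcoords), alpha) - tcrossprod(Wt, Kc)
        diag(C0) <- diag(C0) + .JITTER
        R0 <- chol((C0 + t(C0)) / 2)
        mu <- tcrossprod(etas, Wt)             # nd_a x n0
        eta0[draws, , h] <- if (sample) mu +
          t(crossprod(R0, matrix(rnorm(n0 * length(draws)), n0))) else mu
      } else if (method == "gpp") {
        st <- build_spatial_structure(coords, "gpp", alpha,
                                      knots = object$spec$knots)
        mm <- ncol(st$U)
        # v | eta ~ N(W^-1 U' C^-1 eta, W^-1)
        rhs <- crossprod(st$U, t(etas) / st$c)          # mm x nd_a
        v_mean <- backsolve(st$Wchol,
                            backsolve(st$Wchol, rhs, transpose = TRUE))
        v <- if (sample) v_mean + backsolve(st$Wchol,
                                matrix(rnorm(mm * length(draws)), mm)) else
          v_mean
        K0s <- exp_cov(.dist_cross(newcoords, st$knots), alpha)
        U0 <- t(backsolve(st$chol_star, t(K0s), transpose = TRUE))
        c0 <- pmax(1 - rowSums(U0^2), 0)
        eta0[draws, , h] <- t(U0 %*% v) + if (sample)
          matrix(rnorm(length(draws) * n0), length(draws)) *
            rep(sqrt(c0), each = length(draws)) else 0
      } else {                                  # nngp
        for (i0 in seq_len(n0)) {
          idx <- nn_idx[i0, ]
          Sn <- coords[idx, , drop = FALSE]
          Kn <- exp_cov(.dist_self(Sn), alpha)
          diag(Kn) <- diag(Kn) + .JITTER
          k0 <- exp_cov(.dist_cross(Sn, newcoords[i0, , drop = FALSE]),
                        alpha)[, 1]
          a0 <- solve(Kn, k0)
          v0 <- max(1 - sum(a0 * k0), 0) + .JITTER
          mu <- etas[, idx, drop = FALSE] %*% a0
          eta0[draws, i0, h] <- if (sample)
            mu + sqrt(v0) * rnorm(length(draws)) else mu
        }
      }
    }
  }
  eta0
}

#' Predict from a fitted spatial JSDM
#'
#' Posterior-predictive occurrence probabilities (probit species) or latent
#' means (Gaussian species) at the training sites or at new sites.  For each
#' retained draw the latent factors at new sites are sampled from their
#' conditional distribution under the fitted spatial representation, the
#' linear predictor `L0 = X0 beta + eta0 lambda` is formed, and probabilities
#' `pnorm(L0)` are averaged across draws.
#'
#' @param object a fitted [spjsdm()] model.
#' @param newdata optional list with elements `X` (design matrix, columns
#'   matching the fitted design) and `coords` (site-by-2 matrix).  When
#'   omitted, predictions are made at the training sites using the stored
#'   factor draws.
#' @param type `"response"` (probability for probit species, latent mean for
#'   Gaussian species), `"link"` (latent predictor `L`) or `"richness"`
#'   (per-site expected species richness: the row sum of probabilities).
#' @param posterior if `TRUE`, also return the per-draw array as attribute
#'   `"draws"`.
#' @param ... unused.
#' @return site-by-species matrix of posterior means (or a richness vector).
#' @export
predict.spjsdm <- function(object, newdata = NULL,
                           type = c("response", "link", "richness"),
                           posterior = FALSE, ...) {
  type <- match.arg(type)
  s <- object$samples
  nd <- object$config$n_draws
  probit <- object$data$family == "probit"

  if (is.null(newdata)) {
    X0 <- object$data$X
    eta0 <- s$eta
    if (is.null(eta0)) stop("training-site prediction requires store_latent")
  } else {
    if (is.null(newdata$X) || is.null(newdata$coords))
      stop("`newdata` must be a list with elements `X` and `coords`")
    X0 <- as.matrix(newdata$X)
    if (ncol(X0) != object$data$n_cov)
      stop("covariate mismatch: fitted design has columns [",
           paste(colnames(object$data$X), collapse = ", "),
           "] but `newdata$X` has ", ncol(X0), " columns")
    if (nrow(X0) != nrow(as.matrix(newdata$coords)))
      stop("`newdata$X` and `newdata$coords` must be row-aligned")
    eta0 <- .predict_eta(object, newdata$coords)
  }

  n0 <- nrow(X0); n_s <- object$data$n_species
  acc <- matrix(0, n0, n_s)
  keep <- if (posterior) array(NA_real_, c(nd, n0, n_s)) else NULL
  for (d in seq_len(nd)) {
    L <- linear_predictor(X0, .draw_slice(s$beta, d), .draw_slice(eta0, d),
                          .draw_slice(s$lambda, d))
    if (type != "link")
      L[, probit] <- pnorm(L[, probit, drop = FALSE])
    if (posterior) keep[d, , ] <- L
    acc <- acc + L / nd
  }
  if (type != "link")   # guard against float drift in the across-draw mean
    acc[, probit] <- pmin(pmax(acc[, probit, drop = FALSE], 0), 1)
  dimnames(acc) <- list(NULL, object$data$species_names)
  out <- if (type == "richness") predict_richness(acc) else acc
  if (posterior) attr(out, "draws") <- keep
  out
}

#' Expected species richness from occurrence probabilities
#'
#' @param p site-by-species probability matrix.
#' @return per-site expected richness, `rowSums(p)`, bounded by the number of
#'   species.
#' @examples
#' predict_richness(rbind(c(0.2, 0.3, 0.5)))  # 1
#' @export
predict_richness <- function(p) {
  p <- as.matrix(p)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  rowSums(p)
}

#' Credible-sign-filtered species associations
#'
#' Computes the posterior mean association (correlation-scaled) matrix and
#' flags, at the given credibility threshold, the species pairs whose
#' association sign is consistent across draws: a pair is "credible" when the
#' posterior fraction of draws with positive association is at least `level`
#' or at most `1 - level`.  Non-credible pairs are typically displayed as
#' neutral.
#'
#' @param object a fitted [spjsdm()] model, or a 3-d array of loading draws
#'   (draws x factors x species).
#' @param level credibility threshold in (0.5, 1); default 0.95.
#' @return list with `mean` (posterior mean of the correlation-scaled
#'   association matrix), `support` (logical matrix: sign credibly
#'   estimated), and `prob_positive` (posterior fraction of positive draws).
#' @export
association_support <- function(object, level = 0.95) {
  if (!(is.numeric(level) && length(level) == 1 && level > 0.5 && level < 1))
    stop("`level` must lie in (0.5, 1)")
  lam <- if (inherits(object, "spjsdm")) object$samples$lambda else object
  if (length(dim(lam)) != 3) stop("need a draws x factors x species array")
  nd <- dim(lam)[1]
  if (nd < 2) stop("need at least 2 retained draws")
  mean_om <- 0
  pos <- 0
  for (d in seq_len(nd)) {
    om <- suppressWarnings(association_matrix(.draw_slice(lam, d))$omega_cor)
    mean_om <- mean_om + om / nd
    pos <- pos + (om > 0) / nd
  }
  support <- pos >= level | pos <= 1 - level
  support[is.na(support)] <- FALSE
  list(mean = mean_om, support = support, prob_positive = pos)
}
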