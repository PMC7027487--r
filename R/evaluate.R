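#' Tjur's coefficient of discrimination
#'
#' For binary observations and predicted probabilities,
#' `mean(p[y == 1]) - mean(p[y == 0])`: 1 for perfect separation, 0 for an
#' uninformative predictor.  Undefined when only one class is observed, in
#' which case `NA` is returned (flagged, not an error) so that such species
#' can be excluded from community averages.
#'
#' @param y binary (0/1) vector.
#' @param p probability vector in `[0, 1]`, same length.
#' @return scalar in `[-1, 1]`, or `NA` when `y` is single-class.
#' @examples
#' tjur_r2(c(1, 1, 0, 0), c(0.8, 0.6, 0.2, 0.4))  # 0.4
#' @export
tjur_r2 <- function(y, p) {
  if (length(y) != length(p)) stop("`y` and `p` must have equal length")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  if (all(y == 1) || all(y == 0)) return(NA_real_)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Bernoulli deviance of predicted probabilities
#'
#' `-2 * sum(y log p + (1 - y) log(1 - p))`, with probabilities clipped to
#' `[eps, 1 - eps]` so the value is always finite.
#'
#' @param y binary (0/1) vector.
#' @param p probability vector.
#' @param eps clipping bound (default `1e-12`).
#' @return non-negative scalar.
#' @examples
#' bernoulli_deviance(c(1, 0), c(0.8, 0.3))  # -2 * (log(0.8) + log(0.7))
#' @export
bernoulli_deviance <- function(y, p, eps = 1e-12) {
  if (length(y) != length(p)) stop("`y` and `p` must have equal length")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by the
#' initial-monotone-positive-sequence rule: consecutive autocorrelation pair
#' sums are accumulated while they remain positive, after enforcing
#' monotone non-increase.  The estimate is capped at `n`.  A zero-variance
#' chain has no defined ESS and returns `NA`.
#'
#' @param x numeric vector of draws (length >= 10).
#' @return scalar ESS in `(0, n]`, or `NA` for a constant chain.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 draws")
  v <- var(x)
  if (!is.finite(v) || v <= 0) return(NA_real_)
  lag_max <- min(n - 1, 2000)   # the positivity rule truncates far earlier
  ac <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)      # rho_0 .. rho_lagmax
  # Geyer initial monotone positive sequence on pair sums
  n_pairs <- floor((lag_max + 1) / 2)
  gam <- numeric(n_pairs)
  for (k in seq_len(n_pairs))
    gam[k] <- ac[2 * k - 1] + ifelse(2 * k <= lag_max + 1, ac[2 * k], 0)
  pos <- which(gam <= 0)
  cut <- if (length(pos)) pos[1] - 1 else n_pairs
  if (cut == 0) return(n)
  gam <- cummin(gam[seq_len(cut)])
  tau <- 2 * sum(gam) - 1                       # 1 + 2 sum_{k>=1} rho_k
  min(n / max(tau, 1e-12), n)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt((W (n - 1) / n + B / n) / W)` from the within-chain variance `W` and
#' between-chain variance `B` of two or more equal-length chains.  Values
#' near 1 indicate the chains are sampling the same distribution.
#'
#' @param chains list of (>= 2) equal-length numeric vectors.
#' @return scalar PSRF.
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("`chains` must be a list of at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(means)
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Out-of-sample predictive evaluation of a community model
#'
#' Per-species Tjur R2 and Bernoulli deviance of predicted occurrence
#' probabilities against held-out presence-absence data, with unweighted
#' community means over the species for which the metric is defined (species
#' observed in a single class have undefined Tjur R2 and are excluded from
#' the community mean, but still reported).
#'
#' @param Y site-by-species binary validation matrix.
#' @param P site-by-species predicted probability matrix.
#' @return list with `species` (data frame: species, tjur_r2, deviance) and
#'   `community` (named vector of community means).
#' @export
evaluate_predictions <- function(Y, P) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) stop("`Y` and `P` must have identical shape")
  n_s <- ncol(Y)
  tj <- vapply(seq_len(n_s), function(j) tjur_r2(Y[, j], P[, j]), numeric(1))
  dv <- vapply(seq_len(n_s), function(j) bernoulli_deviance(Y[, j], P[, j]),
               numeric(1))
  sp <- data.frame(species = colnames(Y) %||% paste0("sp", seq_len(n_s)),
                   tjur_r2 = tj, deviance = dv)
  list(species = sp,
       community = c(tjur_r2 = mean(tj, na.rm = TRUE), deviance = mean(dv)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
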