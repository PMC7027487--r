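## Spatial prior machinery for the latent factors.
##
## Each factor has a zero-mean GP prior with exponential covariance
## k(s, s') = exp(-||s - s'||/alpha), unit variance (the factor scale lives in
## the loadings).  A "spatial_structure" holds one factorized representation
## of the implied n_y x n_y prior covariance for a given range alpha:
##   gp   - dense covariance + Cholesky factor
##   gpp  - low-rank basis U (knot predictive process) + diagonal correction c
##          restoring unit marginal variances, K ~= U U' + diag(c)
##   nngp - sparse unit-lower-triangular I - A and diagonal D so that
##          Kinv = (I - A)' Dinv (I - A)
##   iid  - identity covariance (the alpha = 0, nonspatial grid entry)

.JITTER <- 1e-8

#' Exponential spatial covariance
#'
#' `exp(-d/alpha)`: correlation 1 at distance zero, `exp(-1)` at distance
#' `alpha` (the spatial range).
#'
#' @param d non-negative distance (vector/matrix).
#' @param alpha spatial range, strictly positive.
#' @return covariance values in `(0, 1]`.
#' @examples
#' exp_cov(2, 1)  # exp(-2)
#' @export
exp_cov <- function(d, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0)
    stop("`alpha` must be a single positive number (alpha = 0 is the ",
         "nonspatial grid entry and is handled separately)")
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d / alpha)
}

# Cross-distance matrix between two coordinate sets (rows = points).
.dist_cross <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.dist_self <- function(a) .dist_cross(a, a)

#' Hexagonal knot grid for the Gaussian predictive process
#'
#' Places knots on a uniform hexagonal lattice (alternate rows offset by half
#' the spacing, row pitch `sqrt(3)/2` times the spacing) covering the bounding
#' box of the sites, with the spacing chosen so that the lattice size is the
#' smallest attainable count at or above `m_target`.  Degenerate (zero-area)
#' bounding boxes are padded so a valid grid always exists.
#'
#' @param coords site-by-2 coordinate matrix.
#' @param m_target requested number of knots (>= 1).
#' @return list of class `"knot_set"` with `knots` (m*-by-2 matrix),
#'   `m_star` (actual count) and `spacing`.
#' @export
build_knot_grid <- function(coords, m_target) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("need at least one site")
  if (!is.numeric(m_target) || m_target < 1) stop("`m_target` must be >= 1")
  m_target <- as.integer(m_target)

  rng_x <- range(coords[, 1]); rng_y <- range(coords[, 2])
  span <- c(diff(rng_x), diff(rng_y))
  pad <- ifelse(span == 0, pmax(max(span), 1) / 2, 0)
  rng_x <- rng_x + c(-1, 1) * pad[1]
  rng_y <- rng_y + c(-1, 1) * pad[2]
  span <- c(diff(rng_x), diff(rng_y))

  grid_counts <- function(h) {
    nc <- floor(span[1] / h) + 1
    nr <- floor(span[2] / (sqrt(3) / 2 * h)) + 1
    c(nc, nr)
  }
  count <- function(h) prod(grid_counts(h))

  # count(h) is non-increasing; bisect for the largest spacing with
  # count >= m_target (equivalently the smallest attainable count >= target).
  hi <- 2 * max(span) + 1          # one knot
  lo <- max(span) / (2 * (m_target + 2))
  while (count(lo) < m_target) lo <- lo / 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (count(mid) >= m_target) lo <- mid else hi <- mid
  }
  h <- lo
  nn <- grid_counts(h); nc <- nn[1]; nr <- nn[2]

  cx <- mean(rng_x); cy <- mean(rng_y)
  xs <- cx + (seq_len(nc) - (nc + 1) / 2) * h
  ys <- cy + (seq_len(nr) - (nr + 1) / 2) * (sqrt(3) / 2 * h)
  knots <- do.call(rbind, lapply(seq_len(nr), function(r) {
    off <- if (r %% 2 == 0) h / 2 else 0
    cbind(xs + off, rep(ys[r], nc))
  }))
  structure(list(knots = knots, m_star = nrow(knots), spacing = h),
            class = "knot_set")
}

#' Nearest-predecessor neighbour graph for the NNGP
#'
#' Orders the sites by first coordinate (ties: second coordinate, then input
#' index) and assigns to each ordered site the `min(m, i - 1)` nearest
#' preceding sites in Euclidean distance, ties broken toward the smaller
#' ordered index.  This deterministic construction makes NNGP fits
#' reproducible.
#'
#' @param coords site-by-2 coordinate matrix.
#' @param m number of neighbours (>= 1).
#' @return list of class `"neighbor_graph"` with `order` (permutation:
#'   original index of the k-th ordered site), `rank` (inverse permutation)
#'   and `neighbors` (list over ordered sites of ordered-index vectors).
#' @export
build_neighbor_graph <- function(coords, m) {
  coords <- as.matrix(coords)
  if (!is.numeric(m) || m < 1) stop("`m` must be >= 1")
  n <- nrow(coords)
  ord <- order(coords[, 1], coords[, 2], seq_len(n))
  S <- coords[ord, , drop = FALSE]
  D <- .dist_self(S)
  neighbors <- vector("list", n)
  neighbors[[1]] <- integer(0)
  for (i in seq_len(n)[-1]) {
    k <- min(m, i - 1)
    d <- D[i, seq_len(i - 1)]
    neighbors[[i]] <- sort(order(d, seq_len(i - 1))[seq_len(k)])
  }
  rank <- integer(n); rank[ord] <- seq_len(n)
  structure(list(order = ord, rank = rank, neighbors = neighbors, m = m),
            class = "neighbor_graph")
}

#' Build a factorized spatial prior structure
#'
#' Constructs the representation of one latent factor's prior covariance for a
#' given range `alpha` under the requested method.  A jitter of `1e-8` is
#' added to every dense covariance diagonal before factorization.
#'
#' @param coords site-by-2 coordinate matrix.
#' @param method one of `"gp"`, `"gpp"`, `"nngp"`, `"iid"` (identity
#'   covariance; used for the nonspatial `alpha = 0` grid entry).
#' @param alpha spatial range (> 0; ignored for `"iid"`).
#' @param knots a [build_knot_grid()] result (required for `"gpp"`).
#' @param graph a [build_neighbor_graph()] result (required for `"nngp"`).
#' @return object of class `"spatial_structure"`; components depend on the
#'   method, and all carry `logdet` (log-determinant of the implied
#'   covariance) and `n`.
#' @export
build_spatial_structure <- function(coords, method, alpha = NULL,
                                    knots = NULL, graph = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  method <- match.arg(method, c("gp", "gpp", "nngp", "iid"))
  if (method == "iid")
    return(structure(list(method = "iid", alpha = 0, n = n, logdet = 0),
                     class = "spatial_structure"))
  if (is.null(alpha) || alpha <= 0) stop("`alpha` must be > 0 for ", method)

  if (method == "gp") {
    K <- exp_cov(.dist_self(coords), alpha)
    diag(K) <- diag(K) + .JITTER
    R <- tryCatch(chol(K), error = function(e)
      stop("covariance not positive-definite after jitter at alpha = ", alpha))
    return(structure(list(method = "gp", alpha = alpha, n = n, coords = coords,
                          K = K, chol = R, Kinv = chol2inv(R),
                          logdet = 2 * sum(log(diag(R)))),
                     class = "spatial_structure"))
  }

  if (method == "gpp") {
    if (is.null(knots)) stop("`knots` required for method = \"gpp\"")
    S_star <- knots$knots
    Ks <- exp_cov(.dist_self(S_star), alpha)
    diag(Ks) <- diag(Ks) + .JITTER
    Rs <- tryCatch(chol(Ks), error = function(e)
      stop("knot covariance not positive-definite after jitter at alpha = ",
           alpha))
    Kc <- exp_cov(.dist_cross(coords, S_star), alpha)
    U <- t(backsolve(Rs, t(Kc), transpose = TRUE))   # K_{S S*} R^{-1}
    cvec <- pmax(1 - rowSums(U^2), 1e-12)            # Finley correction
    W <- diag(ncol(U)) + crossprod(U, U / cvec)      # I + U' C^-1 U
    Wchol <- chol(W)
    logdet <- 2 * sum(log(diag(Wchol))) + sum(log(cvec))
    return(structure(list(method = "gpp", alpha = alpha, n = n,
                          knots = S_star, chol_star = Rs,
                          U = U, c = cvec, Wchol = Wchol, logdet = logdet),
                     class = "spatial_structure"))
  }

  # nngp
  if (is.null(graph)) stop("`graph` required for method = \"nngp\"")
  ord <- graph$order
  S <- coords[ord, , drop = FALSE]
  nb <- graph$neighbors
  dvec <- numeric(n)
  dvec[1] <- 1 + .JITTER
  ai <- vector("list", n)
  ai[[1]] <- numeric(0)
  for (i in seq_len(n)[-1]) {
    idx <- nb[[i]]
    Sn <- S[idx, , drop = FALSE]
    Kn <- exp_cov(.dist_self(Sn), alpha)
    diag(Kn) <- diag(Kn) + .JITTER
    kv <- exp_cov(.dist_cross(Sn, S[i, , drop = FALSE]), alpha)[, 1]
    a <- drop(solve(Kn, kv))
    di <- 1 + .JITTER - sum(a * kv)
    if (di <= 0)
      stop("non-positive NNGP conditional variance at ordered site ", i,
           " for alpha = ", alpha)
    ai[[i]] <- a
    dvec[i] <- di
  }
  # sparse I - A (ordered space), unit lower triangular
  ii <- rep.int(seq_len(n), lengths(nb))
  jj <- unlist(nb, use.names = FALSE)
  IA <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                             x = c(rep(1, n), -unlist(ai, use.names = FALSE)),
                             dims = c(n, n))
  # precision in original site order: Q_orig = P' Q_ord P with w_ord = w[ord]
  IAr <- IA[, graph$rank, drop = FALSE]              # maps w (orig) -> residuals
  Q <- Matrix::crossprod(Matrix::Diagonal(n, 1 / sqrt(dvec)) %*% IAr)
  structure(list(method = "nngp", alpha = alpha, n = n, graph = graph,
                 a = ai, d = dvec, IA = IA, Q = Q,
                 logdet = sum(log(dvec))),
            class = "spatial_structure")
}

#' @export
print.spatial_structure <- function(x, ...) {
  cat("Spatial structure:", x$method, "| n =", x$n, "| alpha =", x$alpha, "\n")
  invisible(x)
}

#' Dense covariance implied by a spatial structure
#'
#' Reconstructs the full site-by-site prior covariance a structure represents.
#' Intended for checking and small problems (dense in `n`).
#'
#' @param structure a [build_spatial_structure()] result.
#' @return n-by-n covariance matrix.
#' @export
spatial_covariance <- function(structure) {
  n <- structure$n
  switch(structure$method,
    iid  = diag(n),
    gp   = structure$K,
    gpp  = tcrossprod(structure$U) + diag(structure$c, n),
    nngp = {
      L <- solve(structure$IA, diag(sqrt(structure$d), n))  # (I-A)^-1 D^1/2
      Kord <- tcrossprod(as.matrix(L))
      ord <- structure$graph$order
      out <- matrix(0, n, n)
      out[ord, ord] <- Kord
      out
    })
}

#' Sample a latent factor from its spatial prior
#'
#' One zero-mean draw whose covariance is the structure's implied covariance:
#' dense Cholesky for `gp`, `U z_m + sqrt(c) z_n` for `gpp`, and a sparse
#' triangular solve `(I - A) w = sqrt(d) z` for `nngp`.
#'
#' @param structure a [build_spatial_structure()] result.
#' @param n_draws number of independent draws.
#' @return an `n`-vector (`n_draws = 1`) or n-by-`n_draws` matrix.
#' @export
spatial_prior_sample <- function(structure, n_draws = 1) {
  n <- structure$n
  out <- switch(structure$method,
    iid = matrix(rnorm(n * n_draws), n),
    gp  = crossprod(structure$chol, matrix(rnorm(n * n_draws), n)),
    gpp = structure$U %*% matrix(rnorm(ncol(structure$U) * n_draws),
                                 ncol(structure$U)) +
          sqrt(structure$c) * matrix(rnorm(n * n_draws), n),
    nngp = {
      z <- sqrt(structure$d) * matrix(rnorm(n * n_draws), n)
      w_ord <- as.matrix(Matrix::solve(structure$IA, z))
      w <- matrix(0, n, n_draws)
      w[structure$graph$order, ] <- w_ord
      w
    })
  if (n_draws == 1) drop(out) else as.matrix(out)
}

#' Log prior density of a factor vector under a spatial structure
#'
#' Evaluates `log N(w; 0, K)` using the factorized forms: the matrix
#' determinant lemma and Woodbury identity for `gpp`, and the sparse
#' conditional factorization for `nngp`.
#'
#' @param w numeric vector of length `n`.
#' @param structure a [build_spatial_structure()] result.
#' @return log-density (scalar).
#' @export
spatial_log_density <- function(w, structure) {
  if (!all(is.finite(w))) stop("`w` must be finite")
  n <- structure$n
  if (length(w) != n) stop("`w` must have length ", n)
  quad <- switch(structure$method,
    iid = sum(w^2),
    gp  = {
      y <- backsolve(structure$chol, w, transpose = TRUE)
      sum(y^2)
    },
    gpp = {
      wc <- w / structure$c
      s <- crossprod(structure$U, wc)
      y <- backsolve(structure$Wchol, s, transpose = TRUE)
      sum(w * wc) - sum(y^2)
    },
    nngp = {
      r <- as.numeric(structure$IA %*% w[structure$graph$order])
      sum(r^2 / structure$d)
    })
  -0.5 * (n * log(2 * pi) + structure$logdet + quad)
}

# Build one structure per alpha-grid candidate (alpha = 0 -> iid).
.build_structures <- function(coords, method, alpha_grid, m) {
  aux <- NULL
  if (method == "gpp") aux <- build_knot_grid(coords, m)
  if (method == "nngp") aux <- build_neighbor_graph(coords, m)
  structures <- lapply(alpha_grid, function(a) {
    if (a == 0 || method == "none") {
      build_spatial_structure(coords, "iid")
    } else {
      build_spatial_structure(coords, method, alpha = a,
                              knots = aux, graph = aux)
    }
  })
  list(structures = structures, aux = aux)
}
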