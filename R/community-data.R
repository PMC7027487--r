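#' Assemble and validate a community data set
#'
#' Bundles the site-by-species response matrix, the site-level design matrix,
#' site coordinates and (optionally) a species-by-trait design matrix into a
#' validated container used by [spjsdm()] and [simulate_community()].
#'
#' @param Y numeric site-by-species matrix.  For `family = "probit"` species
#'   every entry must be 0 or 1; for `family = "gaussian"` species entries are
#'   real-valued.  Missing values are rejected: the likelihood is defined for
#'   complete records only.
#' @param X numeric site-by-covariate design matrix whose first column must be
#'   the constant 1 (intercept).  If `NULL`, an intercept-only design is used.
#' @param coords numeric site-by-2 matrix of planar (Euclidean) coordinates.
#'   No coordinate-reference-system handling is performed: distances entering
#'   the spatial kernel are plain Euclidean distances in the units supplied.
#' @param traits optional numeric species-by-trait design matrix, first column
#'   constant 1.  When absent a single intercept column is used, so the trait
#'   regression collapses to a common prior mean for the rows of beta.
#' @param family observation model per species: `"probit"` (Bernoulli with
#'   probit link) or `"gaussian"` (identity link, residual variance
#'   `sigma2_j`).  Either a single string recycled to all species or a
#'   character vector of length `ncol(Y)`.
#'
#' @return An object of class `"community_data"`: a list with elements `Y`,
#'   `X`, `coords`, `traits`, `family`, `species_names`, `site_ids` and the
#'   dimensions `n_sites`, `n_species`, `n_cov`, `n_traits`.
#' @examples
#' sim <- simulate_community(n_sites = 60, n_species = 4, seed = 1)
#' dat <- sim$train
#' dat$n_sites
#' @export
community_data <- function(Y, X = NULL, coords, traits = NULL,
                           family = "probit") {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("`Y` must be numeric")
  n_y <- nrow(Y); n_s <- ncol(Y)
  if (is.null(X)) X <- matrix(1, n_y, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  if (nrow(X) != n_y || nrow(coords) != n_y)
    stop("row counts of `Y` (", n_y, "), `X` (", nrow(X), ") and `coords` (",
         nrow(coords), ") must agree")
  if (ncol(coords) != 2) stop("`coords` must have exactly 2 columns")
  if (anyNA(X)) stop("`X` contains missing values")
  if (anyNA(Y)) stop("`Y` contains missing values; complete records required")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(abs(X[, 1] - 1) < 1e-12))
    stop("column 1 of `X` must be the constant intercept 1")

  family <- rep_len(match.arg(family, c("probit", "gaussian"),
                              several.ok = TRUE), n_s)
  bern <- family == "probit"
  if (any(bern) && !all(Y[, bern] %in% c(0, 1)))
    stop("probit species must have responses in {0, 1}")

  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    if (nrow(traits) != n_s)
      stop("`traits` must have one row per species (", n_s, " expected, got ",
           nrow(traits), ")")
    if (anyNA(traits)) stop("`traits` contains missing values")
    if (!all(abs(traits[, 1] - 1) < 1e-12))
      stop("column 1 of `traits` must be the constant intercept 1")
  } else {
    traits <- matrix(1, n_s, 1, dimnames = list(colnames(Y), "(Intercept)"))
  }

  species_names <- colnames(Y)
  if (is.null(species_names)) species_names <- paste0("sp", seq_len(n_s))
  site_ids <- rownames(Y)
  if (is.null(site_ids)) site_ids <- as.character(seq_len(n_y))

  structure(list(Y = Y, X = X, coords = coords, traits = traits,
                 family = family, species_names = species_names,
                 site_ids = site_ids, n_sites = n_y, n_species = n_s,
                 n_cov = ncol(X), n_traits = ncol(traits)),
            class = "community_data")
}

#' @export
print.community_data <- function(x, ...) {
  cat("Community data:", x$n_sites, "sites x", x$n_species, "species\n")
  cat("  covariates:", x$n_cov, " traits:", x$n_traits, "\n")
  cat("  observation model:",
      paste(unique(x$family), collapse = " + "), "\n")
  invisible(x)
}
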