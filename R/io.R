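## Delimited-text I/O.  One tabular dialect throughout: CSV with a header
## row and an identifier first column; JSON for run metadata.  Coordinates
## are planar Euclidean -- no CRS handling is performed anywhere.

.read_table <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(what, " file needs an id column plus data: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in ", what, " file: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", what, " file: ", path)
  rownames(m) <- ids
  m
}

#' Read a community data set from CSV files
#'
#' Reads the response, covariate and coordinate tables (one row per site,
#' first column the site id) and optionally a trait table (one row per
#' species, first column the species id), aligns everything to the site and
#' species order of the response table, and validates the result.
#'
#' @param y_file,x_file,s_file paths to the site-by-species response table,
#'   the site-by-covariate table (first data column the constant 1), and the
#'   site coordinate table (columns `x`, `y`).
#' @param t_file optional path to the species-by-trait table.
#' @param family observation model, as in [community_data()].
#' @return a [community_data()] object.
#' @export
read_community <- function(y_file, x_file, s_file, t_file = NULL,
                           family = "probit") {
  Y <- .read_table(y_file, "response")
  X <- .read_table(x_file, "covariate")
  S <- .read_table(s_file, "coordinate")
  align <- function(m, what) {
    miss <- setdiff(rownames(Y), rownames(m))
    if (length(miss))
      stop("site ids present in response but missing in ", what, ": ",
           paste(head(miss, 5), collapse = ", "))
    m[rownames(Y), , drop = FALSE]
  }
  X <- align(X, "covariates")
  S <- align(S, "coordinates")
  if (!all(c("x", "y") %in% colnames(S)))
    stop("coordinate file must have columns named `x` and `y`")
  S <- S[, c("x", "y")]
  Tm <- NULL
  if (!is.null(t_file)) {
    Tm <- .read_table(t_file, "trait")
    miss <- setdiff(colnames(Y), rownames(Tm))
    if (length(miss))
      stop("species present in response but missing in traits: ",
           paste(head(miss, 5), collapse = ", "))
    Tm <- Tm[colnames(Y), , drop = FALSE]
  }
  community_data(Y, X, S, Tm, family)
}

#' Write a community data set to CSV files
#'
#' Inverse of [read_community()]: writes `Y.csv`, `X.csv`, `S.csv` and (when
#' traits are present) `T.csv` into `dir`.
#'
#' @param data a [community_data()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_community <- function(data, dir) {
  stopifnot(inherits(data, "community_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, ids, idname, fname) {
    df <- data.frame(ids, .fmt_num(m), check.names = FALSE)
    names(df) <- c(idname, colnames(m) %||% paste0("c", seq_len(ncol(m))))
    p <- file.path(dir, fname)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  Y <- data$Y; colnames(Y) <- data$species_names
  S <- data$coords; colnames(S) <- c("x", "y")
  paths <- c(wr(Y, data$site_ids, "site", "Y.csv"),
             wr(data$X, data$site_ids, "site", "X.csv"),
             wr(S, data$site_ids, "site", "S.csv"))
  if (data$n_traits > 1 || any(data$traits != 1))
    paths <- c(paths, wr(data$traits, data$species_names, "species", "T.csv"))
  invisible(paths)
}

# format doubles so that the decimal round trip is lossless
.fmt_num <- function(m) {
  out <- apply(as.matrix(m), 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' Write posterior samples to CSV + JSON
#'
#' One long-format CSV per parameter block (`draw`, index columns, `value`,
#' doubles written losslessly) plus `meta.json` with the seed, the iteration
#' schedule and the retained-draw count.  Round-trips exactly through
#' [read_posterior()].
#'
#' @param fit a fitted [spjsdm()] model.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "spjsdm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fit$samples)) {
    a <- fit$samples[[nm]]
    dims <- dim(a) %||% c(length(a), 1L)
    idx <- do.call(expand.grid, lapply(dims, seq_len))
    names(idx) <- c("draw", "i", "j")[seq_along(dims)]
    df <- idx
    df$value <- sprintf("%.17g", as.numeric(a))
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(package = "spjsdm",
               n_draws = fit$config$n_draws, n_iter = fit$config$n_iter,
               n_burn = fit$config$n_burn, thin = fit$config$thin,
               seed = fit$config$seed,
               spatial = fit$spec$spatial, m = fit$spec$m,
               n_factors = fit$spec$n_factors,
               alpha_grid = fit$spec$alpha_grid,
               n_sites = fit$data$n_sites, n_species = fit$data$n_species,
               species = fit$data$species_names,
               blocks = names(fit$samples),
               dims = lapply(fit$samples, function(a) dim(a) %||% length(a)))
  mp <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read posterior samples written by [write_posterior()]
#'
#' @param dir directory containing the block CSVs and `meta.json`.
#' @return list with `samples` (named list of arrays) and `meta`.
#' @export
read_posterior <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp)) stop("no meta.json in ", dir)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  samples <- list()
  for (nm in meta$blocks) {
    df <- read.csv(file.path(dir, paste0(nm, ".csv")))
    dims <- unlist(meta$dims[[nm]])
    ord <- do.call(order, rev(df[, setdiff(names(df), "value"),
                                 drop = FALSE]))
    samples[[nm]] <- array(as.numeric(df$value[ord]), dims)
  }
  list(samples = samples, meta = meta)
}
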