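## Spatial weights, residual Moran's test, Moran eigenvector maps, and
## forward selection of a spatial filter (SEVM).

#' k-nearest-neighbour spatial weights
#'
#' Binary k-nearest-neighbour connectivity by great-circle distance, with
#' optional row standardization (the default).  The matrix is generally
#' asymmetric; routines that need symmetry (eigenvector extraction)
#' symmetrize it as (W + W') / 2.
#'
#' @param lat,lon site coordinates in decimal degrees.
#' @param k number of neighbours (default 6).
#' @param style `"row"` (row-standardized, default) or `"binary"`.
#' @return An object of class `spatial_weights` with elements `W`, `style`,
#'   `k`.
#' @export
knn_weights <- function(lat, lon, k = 6L, style = c("row", "binary")) {
  style <- match.arg(style)
  n <- length(lat)
  stopifnot(length(lon) == n, n >= 3L, k >= 1L, k < n)
  D <- geosphere::distm(cbind(lon, lat)) / 1000   # km
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    W[i, nb] <- 1
  }
  if (style == "row") W <- W / rowSums(W)
  structure(list(W = W, style = style, k = as.integer(k)),
            class = "spatial_weights")
}

as_weight_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

#' Global Moran's test on regression residuals
#'
#' Moran's I of the residuals, `I = (n / S0) * (e' W e) / (e' e)`, with its
#' expectation and variance under the null of no spatial autocorrelation
#' computed from the regression-residual moments (trace formulas in the
#' annihilator matrix `M = I - X (X'X)^-1 X'`), and a two-sided p-value from
#' the normal approximation.  A permutation p-value (residuals permuted
#' across sites) is available as a cross-check.
#'
#' @param fit a fit from [fit_ols()] (carries residuals and design matrix).
#' @param W spatial weights ([knn_weights()] or a plain matrix).
#' @param method `"moment"` (default) or `"permutation"`.
#' @param n_perm number of permutations for `method = "permutation"`.
#' @param seed seed for the permutation draw.
#' @return A list with `I`, `expectation`, `variance`, `z`, and `p`.
#' @export
morans_test_residuals <- function(fit, W, method = c("moment", "permutation"),
                                  n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  Wm <- as_weight_matrix(W)
  e <- fit$residuals
  X <- fit$X
  n <- length(e)
  stopifnot(nrow(Wm) == n)
  if (var(e) == 0) stop("zero residual variance: Moran's I undefined")
  S0 <- sum(Wm)
  I_obs <- (n / S0) * drop(crossprod(e, Wm %*% e)) / sum(e^2)

  p_mean <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  H <- X %*% XtXi %*% t(X)
  M <- diag(n) - H
  MW <- M %*% Wm
  tr_MW <- sum(diag(MW))
  expectation <- (n / S0) * tr_MW / (n - p_mean)
  MWt <- M %*% t(Wm)
  tr_MWMWt <- sum(MW * t(MWt))
  tr_MWMW <- sum(MW * t(MW))
  variance <- (n / S0)^2 *
    (tr_MWMWt + tr_MWMW + tr_MW^2) /
    ((n - p_mean) * (n - p_mean + 2)) - expectation^2
  z <- (I_obs - expectation) / sqrt(variance)

  if (method == "moment") {
    p <- 2 * pnorm(-abs(z))
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        eb <- e[sample.int(n)]
        (n / S0) * drop(crossprod(eb, Wm %*% eb)) / sum(eb^2)
      }, numeric(1))
    })
    hi <- (1 + sum(perm >= I_obs)) / (n_perm + 1)
    lo <- (1 + sum(perm <= I_obs)) / (n_perm + 1)
    p <- min(1, 2 * min(hi, lo))
  }
  list(I = I_obs, expectation = expectation, variance = variance,
       z = z, p = p)
}

#' Moran eigenvector map basis
#'
#' Eigenvectors of the doubly centred (symmetrized) connectivity matrix
#' `(I - 11'/n) W (I - 11'/n)`, ordered by decreasing eigenvalue, i.e. by
#' decreasing Moran coefficient.  Each vector is mean-zero with unit norm;
#' vectors with positive eigenvalue describe positively autocorrelated
#' spatial patterns and are the candidate spatial-filter covariates.
#'
#' @param W spatial weights ([knn_weights()] or a matrix).
#' @return A list with `vectors` (n x n matrix, columns ordered), `values`,
#'   and `positive` (indices of positive-eigenvalue candidates).
#' @export
mem_eigenvectors <- function(W) {
  Wm <- as_weight_matrix(W)
  n <- nrow(Wm)
  if (n < 3L) stop("need at least 3 sites")
  Ws <- (Wm + t(Wm)) / 2
  cent <- diag(n) - matrix(1 / n, n, n)
  ee <- eigen(cent %*% Ws %*% cent, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ee$values), 1)
  list(vectors = ee$vectors, values = ee$values,
       positive = which(ee$values > tol))
}

#' Forward selection of a spatial filter (SEVM)
#'
#' Greedy selection of Moran eigenvectors to append to a regression until
#' the residual spatial autocorrelation of the *full* model is removed: at
#' each step the candidate eigenvector that most reduces the absolute
#' standardized residual Moran statistic is added; selection stops as soon
#' as the residual Moran p-value exceeds `alpha`, or when no candidate
#' improves.  Only positive-eigenvalue (positively autocorrelated)
#' eigenvectors are candidates.  An empty filter is a valid outcome.
#'
#' @param design a standardized design table (see [build_design()]).
#' @param terms predictors of the full model (all fixed during selection).
#' @param W spatial weights.
#' @param alpha stopping significance level (default 0.05).
#' @param max_candidates optionally restrict to the leading candidates.
#' @param max_vectors cap on the filter size (default n / 4).
#' @return A list with `indices` (columns of `basis$vectors`), `basis` (the
#'   [mem_eigenvectors()] result), `moran_path` (|z| after each addition,
#'   starting with the unfiltered model) and `p` (final residual Moran p).
#' @export
sevm_select_filter <- function(design, terms, W, alpha = 0.05,
                               max_candidates = NULL, max_vectors = NULL) {
  basis <- mem_eigenvectors(W)
  cand <- basis$positive
  if (!is.null(max_candidates)) cand <- head(cand, max_candidates)
  n <- nrow(design)
  max_vectors <- max_vectors %||% max(1L, floor(n / 4))

  filt <- integer(0)
  fit <- fit_ols(design, terms)
  mt <- morans_test_residuals(fit, W)
  path <- abs(mt$z)
  repeat {
    if (mt$p > alpha || length(filt) >= max_vectors || !length(cand)) break
    zs <- vapply(cand, function(j) {
      f <- fit_ols(design, terms,
                   extra = basis$vectors[, c(filt, j), drop = FALSE])
      abs(morans_test_residuals(f, W)$z)
    }, numeric(1))
    best <- which.min(zs)
    if (zs[best] >= abs(mt$z)) break   # no candidate improves
    filt <- c(filt, cand[best])
    cand <- cand[-best]
    fit <- fit_ols(design, terms,
                   extra = basis$vectors[, filt, drop = FALSE])
    mt <- morans_test_residuals(fit, W)
    path <- c(path, abs(mt$z))
  }
  list(indices = filt, basis = basis, moran_path = path, p = mt$p)
}
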