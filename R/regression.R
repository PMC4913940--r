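## OLS regression with AICc all-subsets selection, Akaike-weight variable
## importance, confidence-set model averaging, and the SEVM-filtered variant.

design_predictors <- c("n_species", "elevation", "T_mean", "T_seasonality",
                       "P_ann", "P_seasonality", "human_impact",
                       "T_velocity", "P_velocity")

#' Assemble a regression design table from a site table
#'
#' Extracts the response (`Z_NODF` or `Z_M`) and the nine predictors
#' (species richness, elevation, the four climate normals, human impact,
#' and the two climate-change velocities, which are log-transformed here),
#' dropping rows with undefined values with a logged count.  Coordinates are
#' carried as attributes for the spatial stages.
#'
#' @param sites a site table (see [read_site_table()]).
#' @param response `"Z_NODF"` or `"Z_M"`.
#' @return A `data.frame` of class `design_table` (response column first),
#'   with attributes `response` and `coords`.
#' @export
build_design <- function(sites, response = c("Z_NODF", "Z_M")) {
  response <- match.arg(response)
  df <- as.data.frame(sites)
  if (!response %in% names(df) || all(is.na(df[[response]])))
    stop("site table does not carry the response column ", response)
  out <- df[, c(response, design_predictors)]
  out$T_velocity <- log_transform(out$T_velocity)
  out$P_velocity <- log_transform(out$P_velocity)
  coords <- cbind(lat = df$latitude, lon = df$longitude)
  keep <- stats::complete.cases(out)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with undefined values")
    out <- out[keep, , drop = FALSE]
    coords <- coords[keep, , drop = FALSE]
  }
  if (nrow(out) < ncol(out) + 10L)
    stop("too few rows (", nrow(out), ") for ", ncol(out) - 1L, " predictors")
  structure(out, response = response, coords = coords,
            class = c("design_table", "data.frame"))
}

#' Standardize a design table
#'
#' Centres the response and every predictor to mean 0 and scales to unit
#' standard deviation, so all regression estimates are comparable
#' standardized coefficients.  Idempotent.
#'
#' @param design a design table ([build_design()]), or any numeric
#'   `data.frame` whose first column is the response.
#' @return The standardized design table (attributes preserved).
#' @export
standardize_design <- function(design) {
  for (cc in names(design)) {
    s <- sd(design[[cc]])
    if (!is.finite(s) || s == 0)
      stop("zero-variance column: ", cc)
    design[[cc]] <- (design[[cc]] - mean(design[[cc]])) / s
  }
  design
}

response_name <- function(design) {
  attr(design, "response") %||% names(design)[1]
}

#' Ordinary least-squares fit of a predictor subset
#'
#' Fits the response on an intercept plus the named predictor subset (and
#' any fixed extra columns, e.g. a spatial filter), returning standardized
#' coefficients with two-sided t-test p-values, R-squared, residuals, and
#' AICc computed from the Gaussian profile likelihood with
#' `k = (number of mean parameters) + 1` for the error variance:
#' `AICc = AIC + 2 k (k + 1) / (n - k - 1)`.
#'
#' @param design a standardized design table.
#' @param terms character vector of predictor names.
#' @param extra optional numeric matrix of additional fixed covariates.
#' @return A list of class `fit_result`.
#' @export
fit_ols <- function(design, terms, extra = NULL) {
  y <- design[[response_name(design)]]
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             as.matrix(design[, terms, drop = FALSE]))
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    colnames(extra) <- paste0("MEM", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) || any(abs(diag(ch)) < 1e-10))
    stop("rank-deficient design matrix")
  XtXi <- chol2inv(ch)
  beta <- drop(XtXi %*% crossprod(X, y))
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df_res <- n - ncol(X)
  sigma2 <- rss / df_res
  se <- sqrt(diag(XtXi) * sigma2)
  names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  tss <- sum((y - mean(y))^2)
  k <- ncol(X) + 1
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  aic <- -2 * ll + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(terms = terms, coefficients = beta, se = se, t = tval,
                 p = pval, residuals = res, sigma2 = sigma2,
                 r_squared = 1 - rss / tss, aic = aic, aicc = aicc,
                 loglik = ll, X = X, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("OLS fit: %d terms, R^2 = %.3f, AICc = %.2f\n",
              length(x$terms), x$r_squared, x$aicc))
  invisible(x)
}

#' All-subsets model selection by AICc
#'
#' Fits every subset of the candidate predictors (fixed terms are included
#' in every model), ranks models by AICc, and converts AICc differences into
#' Akaike weights `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`.
#'
#' @param design a standardized design table.
#' @param candidate_terms predictors free to enter or leave (<= 20).
#' @param fixed_terms predictors forced into every model (default
#'   `"n_species"`: associations are sought beyond species richness).
#' @param extra optional fixed covariate matrix (spatial filter), present in
#'   every model.
#' @return A list of class `model_set` with per-model `terms`, `aicc`,
#'   coefficient tables, Akaike `weights`, and `best` (index of the
#'   minimum-AICc model).
#' @export
select_best_aicc <- function(design, candidate_terms,
                             fixed_terms = "n_species", extra = NULL) {
  p <- length(candidate_terms)
  if (p > 20L) stop("more than 20 candidate terms: enumeration is 2^p")
  n_models <- 2^p
  models <- vector("list", n_models)
  aicc <- numeric(n_models)
  for (i in seq_len(n_models)) {
    inc <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(p) - 1L)))
    terms <- c(fixed_terms, candidate_terms[inc])
    fit <- fit_ols(design, terms, extra = extra)
    keep <- c(fixed_terms, candidate_terms[inc])
    models[[i]] <- list(terms = terms,
                        estimate = fit$coefficients[keep],
                        se = fit$se[keep],
                        p = fit$p[keep],
                        aicc = fit$aicc)
    aicc[i] <- fit$aicc
  }
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(list(models = models, aicc = aicc, weights = w,
                 best = which.min(aicc), fixed_terms = fixed_terms,
                 candidate_terms = candidate_terms, extra = extra),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model set: %d models over %d candidate terms; best AICc %.2f\n",
              length(x$models), length(x$candidate_terms),
              x$aicc[x$best]))
  invisible(x)
}

#' Akaike-weight variable importance
#'
#' The relative importance of a predictor is the sum of the Akaike weights
#' of all models that contain it; fixed terms score 1 by construction.
#'
#' @param models a [select_best_aicc()] model set.
#' @return Named numeric vector in \[0, 1\].
#' @export
variable_importance <- function(models) {
  stopifnot(inherits(models, "model_set"))
  terms <- c(models$fixed_terms, models$candidate_terms)
  imp <- vapply(terms, function(v) {
    sum(models$weights[vapply(models$models,
                              function(m) v %in% m$terms, logical(1))])
  }, numeric(1))
  pmin(imp, 1)
}

#' Confidence-set model averaging
#'
#' Retains the smallest set of top-weighted models whose cumulative Akaike
#' weight reaches `conf` (default the 95% confidence set) and averages each
#' coefficient conditionally over the retained models that contain it, with
#' weights renormalized within that subset.  Averaged standard errors use
#' the weighted unconditional-variance formula
#' `se = sqrt(sum_i w_i * (se_i^2 + (b_i - b_avg)^2))` (the revised
#' estimator, which accounts for between-model spread); p-values come from
#' a normal approximation.
#'
#' With `method = "full"`, a coefficient is instead averaged over *all*
#' retained models, entering as 0 where the term is absent (the shrinkage
#' estimator).
#'
#' @param models a [select_best_aicc()] model set.
#' @param conf cumulative-weight threshold (default 0.95).
#' @param method `"conditional"` (subset averaging, default) or `"full"`.
#' @return A `data.frame` with one row per term: `estimate`, `se`, `p`,
#'   `significant` (p < 0.05); attribute `n_retained`.
#' @export
model_average <- function(models, conf = 0.95,
                          method = c("conditional", "full")) {
  method <- match.arg(method)
  stopifnot(inherits(models, "model_set"))
  ord <- order(models$weights, decreasing = TRUE)
  cum <- cumsum(models$weights[ord])
  n_keep <- which(cum >= conf)[1]
  if (is.na(n_keep)) n_keep <- length(ord)
  kept <- ord[seq_len(n_keep)]
  terms <- c(models$fixed_terms, models$candidate_terms)
  rows <- lapply(terms, function(v) {
    idx <- if (method == "conditional") {
      kept[vapply(models$models[kept],
                  function(m) v %in% m$terms, logical(1))]
    } else kept
    if (!length(idx))
      return(data.frame(term = v, estimate = NA_real_, se = NA_real_,
                        p = NA_real_, significant = FALSE))
    w <- models$weights[idx]
    w <- w / sum(w)
    b <- vapply(models$models[idx], function(m)
      if (v %in% m$terms) m$estimate[[v]] else 0, numeric(1))
    s <- vapply(models$models[idx], function(m)
      if (v %in% m$terms) m$se[[v]] else 0, numeric(1))
    est <- sum(w * b)
    se_avg <- sqrt(sum(w * (s^2 + (b - est)^2)))
    pv <- 2 * pnorm(-abs(est / se_avg))
    data.frame(term = v, estimate = est, se = se_avg, p = pv,
               significant = pv < 0.05)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_retained") <- n_keep
  out
}

#' Run the full OLS + SEVM multimodel regression grid
#'
#' Reproduces, for arbitrary input, the complete analysis grid for one
#' response: an OLS full model over all predictors (species richness always
#' included), all-subsets AICc selection with Akaike-weight importance and
#' 95% confidence-set averaging, a global Moran's test on the full- and
#' best-model residuals, then the SEVM pass in which the spatial filter
#' selected by [sevm_select_filter()] is held fixed while the same
#' selection and averaging are repeated.  Associations are flagged
#' significant at p < 0.05.
#'
#' @param design a design table ([build_design()]); standardized internally.
#' @param W spatial weights ([knn_weights()]).
#' @param conf confidence-set level for averaging (default 0.95).
#' @param alpha significance level for the SEVM stopping rule.
#' @param fixed_terms predictors forced into every model.
#' @param max_candidates optional cap on the spatial-filter candidate pool.
#' @return A list of class `regression_suite` with elements `ols`, `sevm`
#'   (each: `full`, `models`, `best_fit`, `averaged`, `importance`,
#'   `moran_full`, `moran_best`), `filter`, and `table` (the formatted
#'   variables-by-models grid; see [format_suite_table()]).
#' @export
run_regression_suite <- function(design, W, conf = 0.95, alpha = 0.05,
                                 fixed_terms = "n_species",
                                 max_candidates = NULL) {
  design <- standardize_design(design)
  terms_all <- setdiff(names(design), response_name(design))
  candidates <- setdiff(terms_all, fixed_terms)

  run_side <- function(extra) {
    full <- fit_ols(design, terms_all, extra = extra)
    ms <- select_best_aicc(design, candidates, fixed_terms, extra = extra)
    best_fit <- fit_ols(design, ms$models[[ms$best]]$terms, extra = extra)
    list(full = full, models = ms, best_fit = best_fit,
         averaged = model_average(ms, conf = conf),
         importance = variable_importance(ms),
         moran_full = morans_test_residuals(full, W),
         moran_best = morans_test_residuals(best_fit, W))
  }

  ols <- run_side(NULL)
  filt <- sevm_select_filter(design, terms_all, W, alpha = alpha,
                             max_candidates = max_candidates)
  Ef <- if (length(filt$indices))
    filt$basis$vectors[, filt$indices, drop = FALSE] else NULL
  sevm <- run_side(Ef)

  out <- structure(list(ols = ols, sevm = sevm, filter = filt,
                        response = response_name(design),
                        terms = terms_all, design = design),
                   class = "regression_suite")
  out$table <- format_suite_table(out)
  out
}

fmt_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))

fmt_est <- function(est, p) {
  ifelse(is.na(est), "", sprintf("%.3f (%s)", est, fmt_p(p)))
}

#' Format a regression suite as a variables-by-models grid
#'
#' Character table with one row per predictor plus Moran's I and R-squared
#' rows, and the eight estimate columns (full, best, averaged, importance,
#' for OLS then SEVM); cells show `estimate (p)` with p-values below 0.01
#' printed as `<0.01`, matching the presentation of the published tables.
#'
#' @param suite a [run_regression_suite()] result.
#' @return A `data.frame` of characters.
#' @export
format_suite_table <- function(suite) {
  stopifnot(inherits(suite, "regression_suite"))
  terms <- suite$terms
  side_cols <- function(side) {
    full <- side$full
    best <- side$best_fit
    avg <- side$averaged
    avg_est <- avg$estimate[match(terms, avg$term)]
    avg_p <- avg$p[match(terms, avg$term)]
    in_best <- terms %in% best$terms
    data.frame(
      full = fmt_est(full$coefficients[terms], full$p[terms]),
      best = ifelse(in_best,
                    fmt_est(best$coefficients[terms], best$p[terms]), ""),
      averaged = fmt_est(avg_est, avg_p),
      importance = sprintf("%.2f", side$importance[terms]),
      stringsAsFactors = FALSE)
  }
  o <- side_cols(suite$ols)
  s <- side_cols(suite$sevm)
  moran <- function(side) {
    c(fmt_est(side$moran_full$I, side$moran_full$p),
      fmt_est(side$moran_best$I, side$moran_best$p), "", "")
  }
  r2 <- function(side) {
    c(sprintf("%.2f", side$full$r_squared),
      sprintf("%.2f", side$best_fit$r_squared), "", "")
  }
  grid <- cbind(o, s)
  names(grid) <- c("OLS_full", "OLS_best", "OLS_averaged", "OLS_importance",
                   "SEVM_full", "SEVM_best", "SEVM_averaged",
                   "SEVM_importance")
  grid <- rbind(grid,
                stats::setNames(as.data.frame(as.list(
                  c(moran(suite$ols), moran(suite$sevm)))), names(grid)),
                stats::setNames(as.data.frame(as.list(
                  c(r2(suite$ols), r2(suite$sevm)))), names(grid)))
  cbind(data.frame(Variables = c(terms, "Moran_I", "R2"),
                   stringsAsFactors = FALSE),
        grid)
}
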