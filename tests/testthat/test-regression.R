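toy_design <- function(n = 30, p = 3, seed = 41, beta = NULL,
                       noise_sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- beta %||% rep(0, p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  df <- data.frame(y = y, X)
  attr(df, "response") <- "y"
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("standardize_design is idempotent and names bad columns", {
  d <- toy_design()
  s1 <- standardize_design(d)
  s2 <- standardize_design(s1)
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-12)
  expect_true(all(abs(colMeans(as.matrix(s1))) < 1e-12))
  expect_true(all(abs(apply(as.matrix(s1), 2, sd) - 1) < 1e-12))
  d$bad <- 5
  expect_error(standardize_design(d), "zero-variance column: bad")
})

test_that("fit_ols matches the closed-form normal-equation solution and lm", {
  d <- standardize_design(toy_design(30, 3, beta = c(1, -0.5, 0)))
  fit <- fit_ols(d, c("x1", "x2", "x3"))
  X <- cbind(1, as.matrix(d[, c("x1", "x2", "x3")]))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(fit$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-9)
  lmf <- lm(y ~ x1 + x2 + x3, data = d)
  sm <- summary(lmf)
  expect_equal(unname(fit$p), unname(sm$coefficients[, 4]),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, sm$r.squared, tolerance = 1e-12)
  expect_equal(fit$aic,
               AIC(lmf), tolerance = 1e-9)   # Gaussian profile likelihood
})

test_that("noiseless linear responses are fit exactly", {
  d <- standardize_design(toy_design(25, 2, beta = c(2, 1), noise_sd = 0))
  fit <- fit_ols(d, c("x1", "x2"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(all(abs(fit$residuals) < 1e-9))
})

test_that("the AICc correction vanishes as n grows at fixed k", {
  small <- standardize_design(toy_design(15, 2))
  big <- standardize_design(toy_design(5000, 2))
  f_s <- fit_ols(small, c("x1", "x2"))
  f_b <- fit_ols(big, c("x1", "x2"))
  k <- 4  # intercept + 2 slopes + error variance
  expect_equal(f_s$aicc - f_s$aic, 2 * k * (k + 1) / (15 - k - 1))
  expect_lt(f_b$aicc - f_b$aic, 0.01)
  expect_error(fit_ols(small, c("x1", "x1")), "rank-deficient")
})

test_that("Akaike weights normalize exp(-delta/2) and find the best model", {
  d <- standardize_design(toy_design(40, 3, beta = c(0.8, 0, 0)))
  ms <- select_best_aicc(d, c("x2", "x3"), fixed_terms = "x1")
  expect_equal(length(ms$models), 4)
  w_oracle <- exp(-(ms$aicc - min(ms$aicc)) / 2)
  w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(ms$weights, w_oracle, tolerance = 1e-12)
  expect_equal(sum(ms$weights), 1, tolerance = 1e-12)
  expect_equal(ms$best, which.min(ms$aicc))
  # delta AICc of 2 implies a weight ratio of exp(1) ~ 0.731 : 0.269
  expect_equal(exp(-0 / 2) / (exp(-0 / 2) + exp(-2 / 2)), 0.731,
               tolerance = 1e-3)
})

test_that("variable importance sums the weights of containing models", {
  d <- standardize_design(toy_design(40, 3, beta = c(0.8, 0.4, 0)))
  ms <- select_best_aicc(d, c("x2", "x3"), fixed_terms = "x1")
  imp <- variable_importance(ms)
  expect_equal(unname(imp["x1"]), 1)   # fixed in every model
  has_x2 <- sapply(ms$models, function(m) "x2" %in% m$terms)
  expect_equal(unname(imp["x2"]), sum(ms$weights[has_x2]),
               tolerance = 1e-12)
  has_x3 <- sapply(ms$models, function(m) "x3" %in% m$terms)
  expect_equal(unname(imp["x3"]), sum(ms$weights[has_x3]),
               tolerance = 1e-12)
})

fake_model_set <- function(weights, models) {
  structure(list(models = models, aicc = -2 * log(weights),
                 weights = weights, best = which.max(weights),
                 fixed_terms = character(0),
                 candidate_terms = unique(unlist(lapply(models,
                                                        `[[`, "terms")))),
            class = "model_set")
}

test_that("conditional model averaging reproduces hand computations", {
  m1 <- list(terms = "x", estimate = c(x = 1.0), se = c(x = 0.1),
             p = c(x = 0.01), aicc = 0)
  m2 <- list(terms = "x", estimate = c(x = 2.0), se = c(x = 0.1),
             p = c(x = 0.01), aicc = 0)
  ms <- fake_model_set(c(0.6, 0.4), list(m1, m2))
  avg <- model_average(ms, conf = 0.95)
  expect_equal(avg$estimate[avg$term == "x"], 0.6 * 1 + 0.4 * 2)
  # revised unconditional-variance standard error, by hand
  se_hand <- sqrt(0.6 * (0.1^2 + (1 - 1.4)^2) +
                    0.4 * (0.1^2 + (2 - 1.4)^2))
  expect_equal(avg$se[avg$term == "x"], se_hand, tolerance = 1e-12)

  # confidence set of size 1: averaged estimates equal the best model's
  ms2 <- fake_model_set(c(0.97, 0.03), list(m1, m2))
  avg2 <- model_average(ms2, conf = 0.95)
  expect_equal(avg2$estimate[avg2$term == "x"], 1.0)

  # three models, one lacking the term: conditional renormalization
  m3 <- list(terms = "z", estimate = c(z = 5), se = c(z = 1),
             p = c(z = 0.01), aicc = 0)
  ms3 <- fake_model_set(c(0.5, 0.3, 0.2), list(m1, m2, m3))
  avg3 <- model_average(ms3, conf = 0.99)
  w <- c(0.5, 0.3) / 0.8
  expect_equal(avg3$estimate[avg3$term == "x"], sum(w * c(1, 2)),
               tolerance = 1e-12)
})

test_that("residual Moran's I gives -1 for a checkerboard on a rook grid", {
  # 2x2 grid, binary rook weights, values 1,0,0,1 (perfect alternation)
  W <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 0, 0, 1), c(0, 1, 1, 0))
  fit <- list(residuals = c(1, 0, 0, 1) - 0.5, X = matrix(1, 4, 1))
  mt <- morans_test_residuals(fit, W)
  expect_equal(mt$I, -1, tolerance = 1e-12)
  expect_error(
    morans_test_residuals(list(residuals = rep(2, 4), X = matrix(1, 4, 1)),
                          W), "zero residual variance")
})

test_that("intercept-only residual Moran matches ape::Moran.I", {
  skip_if_not_installed("ape")
  set.seed(51)
  n <- 25
  W <- matrix(runif(n * n), n, n)
  W <- W * upper.tri(W)
  W <- W + t(W)
  W <- W / rowSums(W)   # ape row-normalizes internally
  x <- rnorm(n)
  fit <- list(residuals = x - mean(x), X = matrix(1, n, 1))
  mine <- morans_test_residuals(fit, W)
  theirs <- ape::Moran.I(x, W, scaled = FALSE)
  expect_equal(mine$I, theirs$observed, tolerance = 1e-9)
})

test_that("moment and permutation Moran p-values agree on clear signals", {
  set.seed(53)
  n <- 40
  lat <- runif(n, 0, 10); lon <- runif(n, 0, 10)
  W <- knn_weights(lat, lon, k = 5)
  d <- data.frame(y = sin(lat) + 0.2 * rnorm(n), x1 = rnorm(n))
  attr(d, "response") <- "y"
  fit <- fit_ols(standardize_design(d), "x1")
  m_mom <- morans_test_residuals(fit, W)
  m_per <- morans_test_residuals(fit, W, method = "permutation",
                                 n_perm = 499, seed = 3)
  expect_lt(m_mom$p, 0.05)
  expect_lt(m_per$p, 0.05)
})

test_that("Moran eigenvectors are centred, orthonormal and sorted", {
  set.seed(55)
  W <- knn_weights(runif(20, 0, 5), runif(20, 0, 5), k = 4)
  mem <- mem_eigenvectors(W)
  V <- mem$vectors
  expect_true(all(abs(colMeans(V[, mem$positive])) < 1e-10))
  G <- crossprod(V)
  expect_true(max(abs(G - diag(ncol(V)))) < 1e-10)
  expect_true(all(diff(mem$values) <= 1e-12))
  expect_error(mem_eigenvectors(matrix(0, 2, 2)), "at least 3")
})

test_that("ring-graph eigenvectors are discrete sinusoids", {
  n <- 16
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1] <- 1
    W[(i %% n) + 1, i] <- 1
  }
  mem <- mem_eigenvectors(W)
  t_idx <- seq_len(n)
  for (j in 1:2) {  # leading pair spans frequency-1 sinusoids
    v <- mem$vectors[, j]
    basis <- cbind(cos(2 * pi * t_idx / n), sin(2 * pi * t_idx / n))
    proj <- basis %*% solve(crossprod(basis), crossprod(basis, v))
    expect_equal(drop(proj), v, tolerance = 1e-8)
  }
})

test_that("greedy filter selection shrinks |Moran z| monotonically", {
  sim <- gen_site_table(60, synthetic_truth(spatial_frac = 1), seed = 61)
  co <- attr(sim$design, "coords")
  W <- knn_weights(co[, "lat"], co[, "lon"], k = 6)
  d <- standardize_design(sim$design)
  terms <- setdiff(names(d), "Z_NODF")
  sel <- sevm_select_filter(d, terms, W, max_candidates = 20)
  expect_true(all(diff(sel$moran_path) <= 1e-12))
  expect_equal(length(sel$indices), length(sel$moran_path) - 1)
})

test_that("the regression suite is deterministic and structured like the
           published grids", {
  sim <- gen_site_table(60, seed = 63)
  co <- attr(sim$design, "coords")
  W <- knn_weights(co[, "lat"], co[, "lon"], k = 6)
  s1 <- run_regression_suite(sim$design, W, max_candidates = 15)
  s2 <- run_regression_suite(sim$design, W, max_candidates = 15)
  expect_identical(s1$table, s2$table)

  tab <- s1$table
  expect_identical(names(tab),
                   c("Variables", "OLS_full", "OLS_best", "OLS_averaged",
                     "OLS_importance", "SEVM_full", "SEVM_best",
                     "SEVM_averaged", "SEVM_importance"))
  expect_identical(tab$Variables,
                   c("n_species", "elevation", "T_mean", "T_seasonality",
                     "P_ann", "P_seasonality", "human_impact", "T_velocity",
                     "P_velocity", "Moran_I", "R2"))
  expect_equal(unname(s1$ols$importance["n_species"]), 1)
  expect_equal(sum(s1$ols$models$weights), 1, tolerance = 1e-12)
})
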