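test_that("generators are pure functions of parameters and seed", {
  expect_identical(gen_bipartite_nested(8, 8, 0.4, 2, seed = 5)$incidence,
                   gen_bipartite_nested(8, 8, 0.4, 2, seed = 5)$incidence)
  expect_identical(gen_foodweb(10, 0.2, 0.1, seed = 5)$adjacency,
                   gen_foodweb(10, 0.2, 0.1, seed = 5)$adjacency)
  expect_identical(gen_bipartite_modular(c(3, 3), c(3, 3), 0.9, 0.05,
                                         seed = 5)$network$incidence,
                   gen_bipartite_modular(c(3, 3), c(3, 3), 0.9, 0.05,
                                         seed = 5)$network$incidence)
  s1 <- gen_site_table(25, seed = 5)
  s2 <- gen_site_table(25, seed = 5)
  expect_identical(s1$sites, s2$sites)
  # generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(gen_foodweb(10, 0.2, 0.1, seed = 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("nested generator hits its target connectance without bias", {
  fills <- sapply(1:300, function(s)
    mean(gen_bipartite_nested(10, 10, 0.5, 0, seed = s)$incidence))
  # conditioning on no empty rows/columns is negligible at this density
  se <- sqrt(0.25 / (100 * 300))
  expect_lt(abs(mean(fills) - 0.5), 4 * se + 0.002)
})

test_that("strong rank bias produces near-perfect nestedness", {
  # at fill 0.6 the staircase limit keeps every row and column occupied
  net <- gen_bipartite_nested(10, 10, 0.6, 25, seed = 7)
  expect_gt(nodf(net), 85)
  expect_gt(nodf(gen_bipartite_nested(10, 10, 0.6, 25, seed = 7)),
            nodf(gen_bipartite_nested(10, 10, 0.6, 0.5, seed = 7)))
})

test_that("planted modular structure is recovered when blocks are disjoint", {
  mod <- gen_bipartite_modular(c(3, 3), c(3, 3), 0.95, 0, seed = 9)
  fit <- maximize_modularity(mod$network, seed = 11)
  crossing <- table(fit$membership, mod$membership)
  expect_true(all(rowSums(crossing > 0) == 1))  # no module straddles blocks
})

test_that("food-web generator respects density and mutual fraction", {
  net <- gen_foodweb(12, 0.2, 0, seed = 13)
  A <- net$adjacency
  expect_equal(sum(A * t(A)), 0)  # no mutual pairs at fraction 0
  dens <- sapply(1:300, function(s) {
    A <- gen_foodweb(12, 0.2, 0.3, seed = s)$adjacency
    sum(A) / (12 * 11)
  })
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 0.2), 3 * se + 0.002)
  mut <- sapply(1:300, function(s) {
    A <- gen_foodweb(12, 0.25, 0.3, seed = s + 500)$adjacency
    sum(A * t(A)) / sum(A)
  })
  expect_lt(abs(mean(mut) - 0.3), 0.04)
  expect_error(gen_foodweb(10, 0.6, 0, seed = 1), "infeasible")
})

test_that("synthetic site tables validate and standardize to the truth", {
  sim <- gen_site_table(80, seed = 15)
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_table(sim$sites, f)
  expect_s3_class(read_site_table(f), "site_table")   # passes validation

  d <- standardize_design(sim$design)
  # predictors restandardize to the latent fields: the true standardized
  # coefficients are recoverable by plain OLS
  fit <- fit_ols(d, c("n_species", "T_mean"))
  expect_lt(abs(fit$coefficients[["n_species"]] - 0.7), 0.15)
  expect_lt(abs(fit$coefficients[["T_mean"]] - 0.3), 0.15)
})

test_that("raster pairs have analytically known velocities", {
  rp <- gen_raster_pair(6, 6, gradient = 0.04, offset = 2, cell_size = 0.5)
  for (r in 2:5) for (c in 2:5) {
    expect_equal(local_slope_4n(rp$current, r, c), 0.04, tolerance = 1e-9)
  }
  cv <- climate_velocity(rp$current, rp$lgm, lat = 1.2, lon = 1.2)
  expect_equal(cv$velocity, 50, tolerance = 1e-9)

  # zero offset: zero velocity everywhere
  rp0 <- gen_raster_pair(6, 6, gradient = 0.04, offset = 0)
  cv0 <- climate_velocity(rp0$current, rp0$lgm, lat = 1.2, lon = 1.2)
  expect_equal(cv0$velocity, 0)

  # with noise, velocity still matches a cellwise oracle recomputation
  rp_n <- gen_raster_pair(6, 6, gradient = 0.04, offset = 2,
                          noise_sd = 0.5, seed = 17)
  cvn <- climate_velocity(rp_n$current, rp_n$lgm, lat = 1.2, lon = 1.2)
  cell <- c(6 - floor(1.2 / 0.5), floor(1.2 / 0.5) + 1)
  want <- abs(rp_n$current$values[cell[1], cell[2]] -
                rp_n$lgm$values[cell[1], cell[2]]) /
    local_slope_4n(rp_n$current, cell[1], cell[2])
  expect_equal(cvn$velocity, want, tolerance = 1e-12)
})
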