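## Generators for networks, site tables and rasters with known ground truth,
## emulating the statistical structure of the study inputs so every pipeline
## stage is testable without external data.  Every generator is a pure
## function of (parameters, seed).

#' Generate a nested bipartite network
#'
#' Cell probabilities decay with the sum of row and column ranks at a rate
#' set by `nestedness_bias` (a logistic threshold on the rank sum, with the
#' threshold solved so the expected fill equals `connectance`);
#' `nestedness_bias = 0` gives uniform random fill at the target
#' connectance, and large bias converges to a deterministic staircase
#' (NODF toward 100).  Draws with an all-zero row or column are resampled.
#'
#' @param n_plants,n_animals matrix dimensions.
#' @param connectance expected fill in (0, 1].
#' @param nestedness_bias decay rate (>= 0).
#' @param seed integer seed.
#' @return A [bipartite_network].
#' @export
gen_bipartite_nested <- function(n_plants, n_animals, connectance,
                                 nestedness_bias = 0, seed = 1L) {
  stopifnot(connectance > 0, connectance <= 1, nestedness_bias >= 0,
            n_plants >= 2, n_animals >= 2)
  if (connectance * n_plants * n_animals < 1)
    stop("expected fill is below one link")
  rr <- if (n_plants > 1) (seq_len(n_plants) - 1) / (n_plants - 1) else 0
  cc <- if (n_animals > 1) (seq_len(n_animals) - 1) / (n_animals - 1) else 0
  ranksum <- outer(rr, cc, "+")
  if (nestedness_bias == 0) {
    P <- matrix(connectance, n_plants, n_animals)
  } else {
    # logistic decay in the rank sum; the threshold is solved so that the
    # expected fill hits the target, and the large-bias limit is a perfect
    # staircase
    thr <- stats::uniroot(function(t) {
      mean(stats::plogis(nestedness_bias * (t - ranksum))) - connectance
    }, lower = min(ranksum) - 40 / nestedness_bias,
       upper = max(ranksum) + 40 / nestedness_bias, tol = 1e-12)$root
    P <- stats::plogis(nestedness_bias * (thr - ranksum))
  }
  M <- with_seed(seed, {
    out <- NULL
    for (try in 1:1000) {
      draw <- matrix(as.numeric(runif(length(P)) < P),
                     n_plants, n_animals)
      if (all(rowSums(draw) > 0) && all(colSums(draw) > 0)) {
        out <- draw
        break
      }
    }
    out
  })
  if (is.null(M))
    stop("could not generate a network without empty rows/columns; ",
         "raise connectance")
  bipartite_network(M)
}

#' Generate a modular (planted-partition) bipartite network
#'
#' Plants and animals are grouped into blocks; links fall within a block
#' with probability `p_within` and between blocks with `p_between`.  The
#' planted partition is returned with the network, for module-recovery
#' checks.
#'
#' @param plants_per_module,animals_per_module integer vectors (one entry
#'   per module, all positive).
#' @param p_within,p_between link probabilities, `p_within > p_between >= 0`.
#' @param seed integer seed.
#' @return A list with `network` ([bipartite_network]) and `membership`
#'   (named planted partition over plants then animals).
#' @export
gen_bipartite_modular <- function(plants_per_module, animals_per_module,
                                  p_within, p_between, seed = 1L) {
  stopifnot(length(plants_per_module) == length(animals_per_module),
            all(plants_per_module >= 1), all(animals_per_module >= 1),
            p_within > p_between, p_between >= 0, p_within <= 1)
  gp <- rep(seq_along(plants_per_module), plants_per_module)
  ga <- rep(seq_along(animals_per_module), animals_per_module)
  P <- ifelse(outer(gp, ga, "=="), p_within, p_between)
  M <- with_seed(seed, {
    out <- NULL
    for (try in 1:1000) {
      draw <- matrix(as.numeric(runif(length(P)) < P), length(gp),
                     length(ga))
      if (all(rowSums(draw) > 0) && all(colSums(draw) > 0)) {
        out <- draw
        break
      }
    }
    out
  })
  if (is.null(M))
    stop("could not generate a network without empty rows/columns; ",
         "raise p_within")
  net <- bipartite_network(M)
  membership <- c(gp, ga)
  names(membership) <- c(net$plant_labels, net$animal_labels)
  list(network = net, membership = membership)
}

#' Generate a random food web
#'
#' Random digraph with expected directed-edge density `connectance` and the
#' stated fraction of edges belonging to mutual (bidirectional) pairs; no
#' self-edges.  Each unordered node pair is independently mutual with
#' probability `connectance * mutual_fraction` and one-way (either
#' direction) with probability `connectance * (1 - mutual_fraction)` each.
#'
#' @param n number of species (>= 3).
#' @param connectance expected density of directed edges in (0, 1).
#' @param mutual_fraction expected fraction of edges that are mutual.
#' @param seed integer seed.
#' @return A [directed_network].
#' @export
gen_foodweb <- function(n, connectance, mutual_fraction = 0, seed = 1L) {
  stopifnot(n >= 3, connectance > 0, connectance < 1,
            mutual_fraction >= 0, mutual_fraction <= 1)
  q_mut <- connectance * mutual_fraction
  q_one <- connectance * (1 - mutual_fraction)
  if (q_mut + 2 * q_one > 1)
    stop("infeasible parameter combination: pair probabilities exceed 1")
  A <- with_seed(seed, {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- runif(1)
        if (u < q_mut) {
          A[i, j] <- A[j, i] <- 1
        } else if (u < q_mut + q_one) {
          A[i, j] <- 1
        } else if (u < q_mut + 2 * q_one) {
          A[j, i] <- 1
        }
      }
    }
    A
  })
  if (sum(A) < 1)
    stop("generated network has no edges; raise connectance")
  directed_network(A)
}

## Exponential-covariance Gaussian process sample on given coordinates
## (direct Cholesky; fine at the study's site counts).
gp_sample <- function(coords, range) {
  D <- as.matrix(dist(coords))
  Sigma <- exp(-D / range)
  L <- chol(Sigma + diag(1e-8, nrow(D)))
  drop(t(L) %*% rnorm(nrow(D)))
}

#' Ground truth for a synthetic study
#'
#' Bundles the known regression truth used by [gen_site_table()]: true
#' standardized coefficients per predictor, the spatial structure of
#' predictors and of the response error, and the coordinate window.
#' Unspecified predictors get a true coefficient of 0.  The residual
#' variance is set to `1 - sum(beta^2)` (floored at `min_error_var`) so the
#' stated effects are true *standardized* coefficients, and is split
#' between a spatially autocorrelated Gaussian-process component (fraction
#' `spatial_frac`, exponential covariance with range `error_range_frac`
#' times the window size) and white noise.
#'
#' @param betas named numeric vector of true standardized effects; names
#'   from the design predictors (`n_species`, `elevation`, `T_mean`,
#'   `T_seasonality`, `P_ann`, `P_seasonality`, `human_impact`,
#'   `T_velocity`, `P_velocity`).  Default: 0.7 on `n_species`, 0.3 on
#'   `T_mean`, 0 elsewhere.
#' @param window degrees, `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param predictor_range_frac GP range of predictor fields as a fraction
#'   of the window size.
#' @param error_range_frac GP range of the response error (default one
#'   quarter of the window).
#' @param spatial_frac fraction of the error variance that is spatially
#'   structured.
#' @param min_error_var floor on the total error variance.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(betas = c(n_species = 0.7, T_mean = 0.3),
                            window = c(0, 10, 0, 10),
                            predictor_range_frac = 0.5,
                            error_range_frac = 0.25,
                            spatial_frac = 0.5,
                            min_error_var = 0.05) {
  bad <- setdiff(names(betas), design_predictors)
  if (length(bad))
    stop("unknown predictor(s) in betas: ", paste(bad, collapse = ", "))
  full <- stats::setNames(numeric(length(design_predictors)),
                          design_predictors)
  full[names(betas)] <- betas
  stopifnot(spatial_frac >= 0, spatial_frac <= 1,
            error_range_frac > 0, predictor_range_frac > 0)
  structure(list(betas = full, window = window,
                 predictor_range_frac = predictor_range_frac,
                 error_range_frac = error_range_frac,
                 spatial_frac = spatial_frac,
                 min_error_var = min_error_var),
            class = "synthetic_truth")
}

#' Generate a synthetic site table with known regression truth
#'
#' Site coordinates are uniform on the truth's window; each predictor is a
#' smooth spatial field plus noise, standardized to the sample; the response
#' is the linear combination under the true coefficients plus a spatially
#' autocorrelated Gaussian error and white noise.  Fields are mapped into
#' plausible units of the site-table schema (0.1 degC for `T_mean`, mm for
#' `P_ann`, a 0-100 footprint score, velocities stored raw via exp so the
#' analysis-time log-transform recovers the linear field).  The response is
#' stored in both `Z_NODF` and `Z_M` (independent error draws).
#'
#' @param n_sites number of sites.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return A list with `sites` (a validated site table) and `design` (the
#'   matching [build_design()] table for response `Z_NODF`).
#' @export
gen_site_table <- function(n_sites, truth = synthetic_truth(), seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_sites >= 20)
  w <- truth$window
  span <- max(w[2] - w[1], w[4] - w[3])
  pred_range <- truth$predictor_range_frac * span
  err_range <- truth$error_range_frac * span
  nugget <- 0.3

  out <- with_seed(seed, {
    lat <- runif(n_sites, w[1], w[2])
    lon <- runif(n_sites, w[3], w[4])
    coords <- cbind(lat, lon)
    fields <- sapply(design_predictors, function(v) {
      f <- sqrt(1 - nugget) * gp_sample(coords, pred_range) +
        sqrt(nugget) * rnorm(n_sites)
      (f - mean(f)) / sd(f)
    })
    lin <- drop(fields %*% truth$betas)
    err_var <- max(truth$min_error_var, 1 - sum(truth$betas^2))
    make_err <- function() {
      sqrt(err_var * truth$spatial_frac) * gp_sample(coords, err_range) +
        sqrt(err_var * (1 - truth$spatial_frac)) * rnorm(n_sites)
    }
    list(lat = lat, lon = lon, fields = fields,
         z_nodf = lin + make_err(), z_m = lin + make_err())
  })

  f <- out$fields
  n_species <- pmax(8, round(30 + 10 * f[, "n_species"]))
  df <- data.frame(
    network_id = sprintf("SYN%03d", seq_len(n_sites)),
    network_kind = rep(c("pollination", "seed_dispersal", "foodweb"),
                       length.out = n_sites),
    binary = TRUE,
    latitude = out$lat,
    longitude = out$lon,
    elevation = 800 + 600 * f[, "elevation"],
    T_mean = 150 + 80 * f[, "T_mean"],
    T_seasonality = 60 + 25 * f[, "T_seasonality"],
    P_ann = pmax(0, 1200 + 400 * f[, "P_ann"]),
    P_seasonality = pmax(0, 40 + 15 * f[, "P_seasonality"]),
    human_impact = pmin(100, pmax(0, 50 + 12 * f[, "human_impact"])),
    T_velocity = exp(f[, "T_velocity"]),
    P_velocity = exp(f[, "P_velocity"]),
    n_species = n_species,
    n_links = pmax(n_species, round(1.8 * n_species)),
    Z_NODF = out$z_nodf,
    Z_M = out$z_m,
    mainland = out$lat > mean(range(out$lat)),
    stringsAsFactors = FALSE)
  ## the count/unit mappings perturb the latent fields (rounding, clipping);
  ## restandardisation happens at analysis time, so the stated betas remain
  ## the standardized truth
  validate_site_table(df)
  class(df) <- c("site_table", "data.frame")
  list(sites = df, design = build_design(df, "Z_NODF"))
}

#' Generate an aligned current/LGM raster pair
#'
#' The current raster is a planar field increasing northward at `gradient`
#' units per km (plus optional white noise); the Last Glacial Maximum
#' raster is the current one minus a uniform (or per-cell) offset.  With no
#' noise the climate-change velocity at every interior cell is analytically
#' `offset / gradient`.
#'
#' @param n_rows,n_cols grid shape (>= 3).
#' @param gradient northward gradient in variable units per km.
#' @param offset temporal offset (scalar or `n_rows x n_cols` matrix).
#' @param cell_size cell size in degrees.
#' @param origin lower-left corner `c(lat, lon)`.
#' @param noise_sd white-noise standard deviation on the current raster.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return A list with `current` and `lgm` ([raster_grid]s).
#' @export
gen_raster_pair <- function(n_rows, n_cols, gradient, offset,
                            cell_size = 0.5, origin = c(0, 0),
                            noise_sd = 0, seed = 1L) {
  stopifnot(n_rows >= 3, n_cols >= 3)
  lat_rows <- origin[1] + (n_rows - seq_len(n_rows) + 0.5) * cell_size
  y_km <- lat_rows * KM_PER_DEGREE
  current <- matrix(rep(gradient * y_km, n_cols), n_rows, n_cols)
  if (noise_sd > 0)
    current <- current +
      with_seed(seed, matrix(rnorm(n_rows * n_cols, sd = noise_sd),
                             n_rows, n_cols))
  if (is.matrix(offset)) stopifnot(identical(dim(offset), dim(current)))
  lgm <- current - offset
  list(current = raster_grid(current, cell_size, origin),
       lgm = raster_grid(lgm, cell_size, origin))
}
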