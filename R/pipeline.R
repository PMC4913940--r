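## End-to-end orchestration: networks -> metrics -> null standardization ->
## design assembly -> OLS suite -> Moran test -> SEVM suite -> output bundle.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object.  The master seed propagates deterministically to every
#' stochastic stage (null ensembles, annealing), so a rerun with the same
#' configuration is bit-identical.
#'
#' @param networks named list of [bipartite_network]/[directed_network]
#'   objects, keyed by `network_id` values of `site_table`.  May be `NULL`
#'   when the site table already carries `Z_NODF`/`Z_M`.
#' @param site_table a site table (see [read_site_table()]).
#' @param responses which standardized metrics to regress.
#' @param n_null null replicates per network (default 500).
#' @param seed master seed.
#' @param k spatial-weights neighbour count.
#' @param alpha significance level (Moran stopping rule and flags).
#' @param conf confidence-set level for model averaging.
#' @param schedule annealing schedule.
#' @param null_variant bipartite null variant.
#' @param max_candidates optional cap on spatial-filter candidates.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(networks = NULL, site_table,
                            responses = c("Z_NODF", "Z_M"),
                            n_null = 500L, seed = 1L, k = 6L,
                            alpha = 0.05, conf = 0.95,
                            schedule = annealing_schedule(),
                            null_variant = "product",
                            max_candidates = NULL, out_dir = NULL) {
  stopifnot(inherits(site_table, "data.frame"), n_null >= 2,
            alpha > 0, alpha < 1, conf > 0, conf < 1)
  responses <- match.arg(responses, several.ok = TRUE)
  if (!is.null(networks)) {
    if (is.null(names(networks)) ||
        !all(names(networks) %in% site_table$network_id))
      stop("networks must be named by site-table network_id values")
  }
  structure(list(networks = networks, site_table = site_table,
                 responses = responses, n_null = as.integer(n_null),
                 seed = as.integer(seed), k = as.integer(k), alpha = alpha,
                 conf = conf, schedule = schedule,
                 null_variant = null_variant,
                 max_candidates = max_candidates, out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load/validate networks; compute NODF and modularity;
#' standardize both against the null model matching each network's kind
#' (edge switching for food webs, degree-probability for mutualistic webs);
#' assemble the design table (velocities log-transformed); run the OLS
#' multimodel suite; Moran's test; the SEVM suite; write the
#' variables-by-models CSV grids, residual scatter data (response vs each
#' predictor, both as SEVM best-model residuals), and a plain-text run
#' manifest.  Any stage failure aborts with a stage-named message.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with the augmented site table,
#'   one [run_regression_suite()] result per response, the scatter data,
#'   and the manifest lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sites <- config$site_table

  if (!is.null(config$networks)) {
    seeds <- spawn_seeds(config$seed, length(config$networks))
    metrics <- stage("metrics", {
      ids <- names(config$networks)
      res <- lapply(seq_along(ids), function(i) {
        net <- config$networks[[i]]
        zn <- standardize_metric(net, "NODF", n_null = config$n_null,
                                 seed = seeds[i],
                                 null_variant = config$null_variant)
        zm <- standardize_metric(net, "M", n_null = config$n_null,
                                 seed = seeds[i] + 1L,
                                 schedule = config$schedule,
                                 null_variant = config$null_variant)
        c(Z_NODF = zn$z, Z_M = zm$z,
          NODF = zn$x_real, M = zm$x_real)
      })
      do.call(rbind, res)
    })
    idx <- match(names(config$networks), sites$network_id)
    for (cc in c("Z_NODF", "Z_M", "NODF_raw", "M_raw"))
      if (is.null(sites[[cc]])) sites[[cc]] <- NA_real_
    sites$Z_NODF[idx] <- metrics[, "Z_NODF"]
    sites$Z_M[idx] <- metrics[, "Z_M"]
    sites$NODF_raw[idx] <- metrics[, "NODF"]
    sites$M_raw[idx] <- metrics[, "M"]
  }

  stage("design", {
    if (is.null(sites$latitude) || anyNA(sites$latitude) ||
        is.null(sites$longitude) || anyNA(sites$longitude)) {
      bad <- which(is.na(sites$latitude) | is.na(sites$longitude))
      stop("site table missing coordinates at row(s) ",
           paste(bad, collapse = ", "))
    }
  })

  suites <- list()
  scatter <- list()
  for (resp in config$responses) {
    design <- stage("design", build_design(sites, resp))
    coords <- attr(design, "coords")
    W <- stage("spatial_weights",
               knn_weights(coords[, "lat"], coords[, "lon"], k = config$k))
    suite <- stage("regression",
                   run_regression_suite(design, W, conf = config$conf,
                                        alpha = config$alpha,
                                        max_candidates =
                                          config$max_candidates))
    suites[[resp]] <- suite
    scatter[[resp]] <- stage("scatter", residual_scatter(suite))
  }

  manifest <- c(
    sprintf("econetclim pipeline run (%s)", format(Sys.time(), "%Y-%m-%d")),
    sprintf("package version: %s",
            as.character(utils::packageVersion("econetclim"))),
    sprintf("R version: %s", getRversion()),
    sprintf("master seed: %d", config$seed),
    sprintf("n_null: %d", config$n_null),
    sprintf("spatial weights: k-nearest neighbours, k = %d", config$k),
    sprintf("alpha: %g; confidence set: %g", config$alpha, config$conf),
    sprintf("bipartite null variant: %s", config$null_variant),
    sprintf("annealing: cooling %g, tmin_ratio %g, moves_factor %g, restarts %d",
            config$schedule$cooling, config$schedule$tmin_ratio,
            config$schedule$moves_factor, config$schedule$restarts),
    sprintf("networks analysed: %d",
            length(config$networks %||% list())),
    sprintf("sites: %d", nrow(sites)),
    sprintf("responses: %s", paste(config$responses, collapse = ", ")))

  out <- structure(list(sites = sites, suites = suites, scatter = scatter,
                        manifest = manifest, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) stage("write", write_bundle(out))
  out
}

## Residuals of the response and of each predictor against the SEVM
## best-model covariates (added-variable style scatter data).
residual_scatter <- function(suite) {
  design <- suite$design
  best <- suite$sevm$best_fit
  filt <- suite$filter
  Ef <- if (length(filt$indices))
    filt$basis$vectors[, filt$indices, drop = FALSE] else NULL
  resp <- response_name(design)
  lapply(stats::setNames(nm = best$terms), function(v) {
    others <- setdiff(best$terms, v)
    X <- cbind(1, as.matrix(design[, others, drop = FALSE]), Ef)
    qx <- qr(X)
    data.frame(predictor_residual = qr.resid(qx, design[[v]]),
               response_residual = qr.resid(qx, design[[resp]]))
  })
}

write_bundle <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- result$config$out_dir
  write_site_table(result$sites, file.path(od, "site_table.csv"))
  for (resp in names(result$suites)) {
    write.table(result$suites[[resp]]$table,
                file.path(od, sprintf("regression_%s.csv", resp)),
                sep = ",", quote = TRUE, row.names = FALSE)
    for (v in names(result$scatter[[resp]]))
      write.table(result$scatter[[resp]][[v]],
                  file.path(od, sprintf("scatter_%s_%s.csv", resp, v)),
                  sep = ",", quote = FALSE, row.names = FALSE)
  }
  writeLines(result$manifest, file.path(od, "manifest.txt"))
  invisible(od)
}

#' Run the pipeline on mainland/island subsets
#'
#' Executes the pipeline per subset with shared seeds.  `subset = "all"`
#' works on any table; the mainland/island subsets require a logical
#' `mainland` column.
#'
#' @param config a [pipeline_config()].
#' @param subset one or more of `"all"`, `"mainland"`, `"island"`.
#' @return A named list of [run_pipeline()] results.
#' @export
subset_runs <- function(config, subset = "all") {
  subset <- match.arg(subset, c("all", "mainland", "island"),
                      several.ok = TRUE)
  lapply(stats::setNames(nm = subset), function(s) {
    cfg <- config
    if (s != "all") {
      if (is.null(cfg$site_table$mainland))
        stop("subset '", s, "' requested but the site table has no ",
             "mainland flag column")
      keep <- if (s == "mainland") cfg$site_table$mainland
              else !cfg$site_table$mainland
      if (!any(keep)) stop("subset '", s, "' selects 0 rows")
      cfg$site_table <- cfg$site_table[keep, , drop = FALSE]
      if (!is.null(cfg$networks))
        cfg$networks <- cfg$networks[names(cfg$networks) %in%
                                       cfg$site_table$network_id]
      if (!is.null(cfg$out_dir))
        cfg$out_dir <- file.path(cfg$out_dir, s)
    }
    run_pipeline(cfg)
  })
}
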