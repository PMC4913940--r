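## Degree-preserving null models and Z-score standardization of metrics.

#' Degree-preserving edge switching for directed networks
#'
#' Randomizes a food web by repeatedly rewiring two randomly selected edges.
#' One-way and mutual edges are switched in separate pools so that every
#' node's counts of one-way incoming, one-way outgoing, and mutual edges are
#' exactly preserved: a proposed swap of one-way edges A->B and C->D yields
#' A->D and C->B, and of mutual pairs A<->B and C<->D yields A<->D and
#' C<->B; a proposal is applied only if it creates no self-edges and no
#' multiple edges (including no one-way edge that would pair with an
#' existing opposite edge into a mutual one).  Illegal proposals are
#' rejected and retried.
#'
#' @param net a [directed_network].
#' @param seed integer seed.
#' @param n_swaps target number of accepted swaps (default 10 x edge count).
#' @param max_attempts attempt budget; if exhausted the network is returned
#'   as randomized so far (possibly unchanged, e.g. for a 3-cycle where no
#'   swap is legal).
#' @return A [directed_network] with identical per-node degree triples.
#' @export
switch_edges_directed <- function(net, seed = 1L, n_swaps = NULL,
                                  max_attempts = NULL) {
  stopifnot(inherits(net, "directed_network"))
  A <- net$adjacency
  n_edges <- sum(A)
  n_swaps <- n_swaps %||% (10L * n_edges)
  max_attempts <- max_attempts %||% max(1000L, 100L * n_swaps)

  sym <- A * t(A)
  one <- which(A == 1 & sym == 0, arr.ind = TRUE)          # one-way edges
  mut <- which(sym == 1 & upper.tri(sym), arr.ind = TRUE)  # mutual pairs
  n_one <- nrow(one)
  n_mut <- nrow(mut)

  with_seed(seed, {
    accepted <- 0L
    attempts <- 0L
    while (accepted < n_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      pools <- c(one = n_one >= 2, mut = n_mut >= 2)
      if (!any(pools)) break
      use_one <- if (all(pools)) runif(1) < n_one / (n_one + n_mut)
                 else pools[["one"]]
      if (use_one) {
        e <- sample.int(n_one, 2L)
        a <- one[e[1], 1]; b <- one[e[1], 2]
        c_ <- one[e[2], 1]; d <- one[e[2], 2]
        # propose a->d, c->b
        if (a == d || c_ == b) next
        if (A[a, d] == 1 || A[d, a] == 1 || A[c_, b] == 1 || A[b, c_] == 1)
          next
        A[a, b] <- 0; A[c_, d] <- 0
        A[a, d] <- 1; A[c_, b] <- 1
        one[e[1], ] <- c(a, d)
        one[e[2], ] <- c(c_, b)
      } else {
        e <- sample.int(n_mut, 2L)
        a <- mut[e[1], 1]; b <- mut[e[1], 2]
        c_ <- mut[e[2], 1]; d <- mut[e[2], 2]
        # propose a<->d, c<->b
        if (a == d || c_ == b) next
        if (A[a, d] == 1 || A[d, a] == 1 || A[c_, b] == 1 || A[b, c_] == 1)
          next
        A[a, b] <- 0; A[b, a] <- 0; A[c_, d] <- 0; A[d, c_] <- 0
        A[a, d] <- 1; A[d, a] <- 1; A[c_, b] <- 1; A[b, c_] <- 1
        mut[e[1], ] <- c(a, d)
        mut[e[2], ] <- c(c_, b)
      }
      accepted <- accepted + 1L
    }
  })
  out <- directed_network(A, net$node_labels)
  attr(out, "accepted_swaps") <- accepted
  out
}

#' Degree-probability null model for bipartite networks
#'
#' Generates a random bipartite network in which the probability that plant i
#' connects to animal j is proportional to the product of their observed
#' degrees: `p_ij = min(1, k_i * d_j / L)` (the default, matching the
#' product-of-degrees description), or, with `variant = "average"`, the
#' averaged-fill cell probability `(k_i / C + d_j / R) / 2` of the classical
#' probabilistic null model II.  Matrices with an all-zero row or column are
#' resampled (the metrics are undefined for them), up to `max_tries` times.
#'
#' @param net a [bipartite_network].
#' @param seed integer seed.
#' @param variant `"product"` (default) or `"average"`.
#' @param max_tries resampling budget for empty rows/columns.
#' @return A [bipartite_network] with the same labels.
#' @export
null_bipartite_degreeprob <- function(net, seed = 1L,
                                      variant = c("product", "average"),
                                      max_tries = 1000L) {
  stopifnot(inherits(net, "bipartite_network"))
  variant <- match.arg(variant)
  B <- net$incidence
  R <- nrow(B); C <- ncol(B)
  k <- rowSums(B); d <- colSums(B); L <- sum(B)
  P <- if (variant == "product") pmin(outer(k, d) / L, 1)
       else (matrix(k / C, R, C) + matrix(d / R, R, C, byrow = TRUE)) / 2
  M <- with_seed(seed, {
    out <- NULL
    for (try in seq_len(max_tries)) {
      draw <- matrix(as.numeric(runif(R * C) < P), R, C)
      if (all(rowSums(draw) > 0) && all(colSums(draw) > 0)) {
        out <- draw
        break
      }
    }
    out
  })
  if (is.null(M))
    stop("could not draw a null matrix without empty rows/columns in ",
         max_tries, " tries")
  bipartite_network(M, net$plant_labels, net$animal_labels)
}

#' Null ensemble of metric values
#'
#' Container for a metric evaluated on null-model replicates, carrying the
#' ensemble mean `x_null` and standard deviation `sd_null` used for Z-score
#' standardization.
#'
#' @param values numeric vector of metric values, one per replicate (>= 2).
#' @param metric_name metric label (e.g. `"NODF"` or `"M"`).
#' @return An object of class `null_ensemble`.
#' @export
null_ensemble <- function(values, metric_name = "metric") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a null ensemble needs at least 2 replicates")
  structure(list(metric_name = metric_name, values = values,
                 x_null = mean(values), sd_null = sd(values),
                 n_replicates = length(values)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null ensemble for %s: n = %d, mean = %.4f, sd = %.4f\n",
              x$metric_name, x$n_replicates, x$x_null, x$sd_null))
  invisible(x)
}

#' Z-score of an observed metric against a null ensemble
#'
#' `Z = (X_real - X_null) / SD_null`, with `X_null` and `SD_null` the mean
#' and standard deviation over the null replicates.
#'
#' @param x_real observed metric value.
#' @param ensemble a [null_ensemble()].
#' @return The Z-score.
#' @export
z_score <- function(x_real, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$sd_null == 0)
    stop("degenerate null ensemble for ", ensemble$metric_name,
         ": zero standard deviation")
  (x_real - ensemble$x_null) / ensemble$sd_null
}

#' Standardize a network metric against its degree-preserving null
#'
#' Generates `n_null` null replicates with the model matching the network
#' kind (edge switching for directed food webs, the degree-probability model
#' for bipartite mutualistic webs), evaluates the requested metric on each
#' (NODF on food webs is computed on the resource-consumer bipartite form;
#' the annealer is reseeded per replicate), and returns the Z-score together
#' with the ensemble.  Deterministic given `seed`.
#'
#' @param net a [bipartite_network] or [directed_network].
#' @param metric `"NODF"` or `"M"`.
#' @param n_null number of null replicates (default 500).
#' @param seed integer master seed.
#' @param schedule annealing schedule for `metric = "M"`.
#' @param null_variant bipartite null variant, see
#'   [null_bipartite_degreeprob()].
#' @return A list with `z`, `x_real`, and `ensemble`.
#' @export
standardize_metric <- function(net, metric = c("NODF", "M"), n_null = 500L,
                               seed = 1L, schedule = annealing_schedule(),
                               null_variant = "product") {
  metric <- match.arg(metric)
  if (n_null < 2L) stop("n_null must be at least 2")
  directed <- inherits(net, "directed_network")
  if (!directed && !inherits(net, "bipartite_network"))
    stop("net must be a bipartite_network or directed_network")
  seeds <- spawn_seeds(seed, n_null + 1L)

  eval_metric <- function(x, s) {
    if (metric == "NODF") {
      nodf(if (inherits(x, "directed_network")) foodweb_to_bipartite(x) else x)
    } else {
      maximize_modularity(x, seed = s, schedule = schedule)$value
    }
  }
  draw_null <- function(s) {
    if (directed) switch_edges_directed(net, seed = s)
    else null_bipartite_degreeprob(net, seed = s, variant = null_variant)
  }
  x_real <- eval_metric(net, seeds[n_null + 1L])
  values <- vapply(seq_len(n_null), function(b) {
    eval_metric(draw_null(seeds[b]), seeds[b])
  }, numeric(1))
  ens <- null_ensemble(values, metric)
  list(z = z_score(x_real, ens), x_real = x_real, ensemble = ens)
}

#' Write a null ensemble to CSV
#'
#' One row per replicate (`replicate`, `value`), for audit trails.
#'
#' @param ensemble a [null_ensemble()].
#' @param path output CSV path.
#' @export
write_null_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  write.table(data.frame(replicate = seq_along(ensemble$values),
                         value = ensemble$values),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
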