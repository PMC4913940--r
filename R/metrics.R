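## Structural metrics: NODF nestedness and modularity (bipartite Barber form
## and Leicht-Newman directed form), with simulated-annealing maximisation.

#' NODF nestedness of a bipartite network
#'
#' NODF averages, over all row pairs and all column pairs, a paired-overlap
#' percentage: for a pair (u, v) with strictly larger marginal total in u,
#' the contribution is 100 * |ones(v) intersect ones(u)| / |ones(v)|; pairs
#' with equal marginal totals contribute exactly 0 (the decreasing-fill
#' rule).  The result lies in \[0, 100\]; higher values mean specialists
#' interact with subsets of the partners of generalists.
#'
#' @param net a [bipartite_network] with no all-zero rows or columns.
#' @return NODF score in \[0, 100\].
#' @export
nodf <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  B <- net$incidence
  if (nrow(B) < 2L && ncol(B) < 2L)
    stop("NODF needs at least 2 rows or 2 columns")
  if (any(rowSums(B) == 0) || any(colSums(B) == 0))
    stop("NODF is undefined with all-zero rows or columns")
  pair_sum <- function(M) {
    n <- nrow(M)
    if (n < 2L) return(c(0, 0))
    fills <- rowSums(M)
    ov <- M %*% t(M)                      # pairwise shared ones
    fi <- matrix(fills, n, n)             # fill of i (row index)
    fj <- t(fi)                           # fill of j
    lo <- pmin(fi, fj)
    contrib <- ifelse(fi == fj, 0, 100 * ov / lo)
    c(sum(contrib[upper.tri(contrib)]), n * (n - 1) / 2)
  }
  s <- pair_sum(B) + pair_sum(t(B))
  as.numeric(s[1] / s[2])
}

as_modularity_matrix <- function(net) {
  if (inherits(net, "bipartite_network")) {
    list(W = net$incidence, directed = FALSE,
         labels = c(net$plant_labels, net$animal_labels))
  } else if (inherits(net, "directed_network")) {
    list(W = net$adjacency, directed = TRUE, labels = net$node_labels)
  } else stop("net must be a bipartite_network or directed_network")
}

check_membership <- function(membership, labels) {
  if (!is.null(names(membership))) {
    missing <- setdiff(labels, names(membership))
    if (length(missing))
      stop("partition is missing node(s): ", paste(missing, collapse = ", "))
    membership <- membership[labels]
  } else if (length(membership) != length(labels)) {
    stop("partition covers ", length(membership), " nodes but the network has ",
         length(labels))
  }
  as.integer(membership)
}

modularity_score_matrix <- function(W, directed, g) {
  m <- sum(W)
  nr <- nrow(W); nc <- ncol(W)
  grow <- g[seq_len(nr)]
  gcol <- if (directed) g else g[nr + seq_len(nc)]
  expected <- outer(rowSums(W), colSums(W)) / m
  same <- outer(grow, gcol, "==")
  sum((W - expected)[same]) / m
}

#' Bipartite (Barber) modularity of a partition
#'
#' Q = (1/L) * sum_ij (B_ij - k_i d_j / L) delta(g_i, g_j), where k_i and d_j
#' are plant and animal degrees and L the number of links; the sum runs over
#' plant-animal pairs only.
#'
#' @param net a [bipartite_network].
#' @param membership integer module assignment over the nodes (plants first,
#'   then animals), or a vector named by node label.
#' @return Modularity score (at most 1).
#' @export
bipartite_modularity <- function(net, membership) {
  stopifnot(inherits(net, "bipartite_network"))
  g <- check_membership(membership,
                        c(net$plant_labels, net$animal_labels))
  modularity_score_matrix(net$incidence, FALSE, g)
}

#' Directed (Leicht-Newman) modularity of a partition
#'
#' Q = (1/m) * sum_ij (A_ij - k_i^out k_j^in / m) delta(g_i, g_j), with m the
#' number of directed edges.
#'
#' @param net a [directed_network].
#' @param membership integer module assignment over nodes (optionally named).
#' @return Modularity score (at most 1).
#' @export
directed_modularity <- function(net, membership) {
  stopifnot(inherits(net, "directed_network"))
  g <- check_membership(membership, net$node_labels)
  modularity_score_matrix(net$adjacency, TRUE, g)
}

#' Simulated-annealing schedule
#'
#' Controls for [maximize_modularity()].  The initial temperature is chosen
#' automatically (from sampled move sizes, so that most early proposals are
#' accepted) unless given; cooling is geometric; the chain length per
#' temperature is proportional to n^2 single-node moves plus n collective
#' (merge/split) moves; several independent restarts are run and the best
#' partition kept.
#'
#' @param t0 initial temperature (> 0), or `NULL` to auto-tune.
#' @param cooling geometric cooling factor in (0, 1).
#' @param tmin_ratio stop when temperature falls below `t0 * tmin_ratio`.
#' @param moves_factor multiplier on the per-temperature chain length.
#' @param restarts number of independent annealing restarts (>= 1).
#' @return A list of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t0 = NULL, cooling = 0.995,
                               tmin_ratio = 1e-4, moves_factor = 1,
                               restarts = 3L) {
  if (!is.null(t0) && (!is.finite(t0) || t0 <= 0))
    stop("initial temperature must be positive")
  if (!is.finite(cooling) || cooling <= 0 || cooling >= 1)
    stop("cooling factor must lie strictly inside (0, 1)")
  stopifnot(tmin_ratio > 0, tmin_ratio < 1, moves_factor > 0, restarts >= 1)
  structure(list(t0 = t0, cooling = cooling, tmin_ratio = tmin_ratio,
                 moves_factor = moves_factor, restarts = as.integer(restarts)),
            class = "annealing_schedule")
}

#' Maximise modularity by simulated annealing
#'
#' Searches the partition space with single-node reassignments plus module
#' merges and random-bisection splits, accepting uphill moves always and
#' downhill moves with Boltzmann probability.  Annealing limits the
#' resolution problem of greedy modularity optimisation.  The single-module
#' partition (Q = 0) is always a candidate, so the result is never negative.
#' Deterministic given `seed`.
#'
#' @param net a [bipartite_network] or [directed_network].
#' @param seed integer seed for the annealer's private RNG.
#' @param schedule an [annealing_schedule()].
#' @return A list of class `modularity_fit` with `value` (the best Q found),
#'   `membership` (named module assignment, indices contiguous from 1) and
#'   `n_modules`.
#' @export
maximize_modularity <- function(net, seed = 1L,
                                schedule = annealing_schedule()) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  mm <- as_modularity_matrix(net)
  res <- anneal_modularity_cpp(mm$W, mm$directed, as.integer(seed),
                               schedule$t0 %||% -1, schedule$cooling,
                               schedule$tmin_ratio, schedule$moves_factor,
                               schedule$restarts)
  membership <- res$membership + 1L
  names(membership) <- mm$labels
  structure(list(name = "M", value = res$Q, membership = membership,
                 n_modules = res$n_modules),
            class = "modularity_fit")
}

#' @export
print.modularity_fit <- function(x, ...) {
  cat(sprintf("modularity fit: M = %.6f over %d modules\n",
              x$value, x$n_modules))
  invisible(x)
}
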