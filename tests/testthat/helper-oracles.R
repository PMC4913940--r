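# Independent brute-force oracles (explicit loops, no shared code with the
# package implementations) and small fixture generators.

naive_nodf <- function(B) {
  contrib <- numeric(0)
  for (M in list(B, t(B))) {
    n <- nrow(M)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fi <- sum(M[i, ]); fj <- sum(M[j, ])
        if (fi == fj) {
          contrib <- c(contrib, 0)
        } else {
          hi <- if (fi > fj) i else j
          lo <- if (fi > fj) j else i
          shared <- sum(M[hi, ] == 1 & M[lo, ] == 1)
          contrib <- c(contrib, 100 * shared / sum(M[lo, ]))
        }
      }
    }
  }
  mean(contrib)
}

naive_bipartite_Q <- function(B, g) {
  L <- sum(B)
  k <- rowSums(B); d <- colSums(B)
  R <- nrow(B); C <- ncol(B)
  q <- 0
  for (i in seq_len(R))
    for (j in seq_len(C))
      if (g[i] == g[R + j]) q <- q + B[i, j] - k[i] * d[j] / L
  as.numeric(q / L)
}

naive_directed_Q <- function(A, g) {
  m <- sum(A)
  kout <- rowSums(A); kin <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (g[i] == g[j]) q <- q + A[i, j] - kout[i] * kin[j] / m
  as.numeric(q / m)
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recur <- function(g, k) {
    i <- length(g) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- g
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) recur(c(g, lab), max(k, lab))
  }
  recur(integer(0), 0L)
  out
}

exhaustive_modularity <- function(net) {
  if (inherits(net, "bipartite_network")) {
    B <- net$incidence
    n <- nrow(B) + ncol(B)
    score <- function(g) naive_bipartite_Q(B, g)
  } else {
    A <- net$adjacency
    n <- nrow(A)
    score <- function(g) naive_directed_Q(A, g)
  }
  best <- -Inf
  for (g in all_partitions(n)) {
    q <- score(g)
    if (q > best) best <- q
  }
  best
}

# Random binary matrix with no all-zero rows/columns (rejection sampling;
# caller sets the RNG state).
random_incidence <- function(R, C, p = 0.4) {
  repeat {
    M <- matrix(rbinom(R * C, 1, p), R, C)
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) return(M)
  }
}

random_adjacency <- function(n, p = 0.3) {
  repeat {
    A <- matrix(rbinom(n * n, 1, p), n, n)
    diag(A) <- 0
    if (sum(A) >= 1) return(A)
  }
}

# Per-node (one-way in, one-way out, mutual) degree triple of an adjacency
# matrix.
degree_triples <- function(A) {
  sym <- A * t(A)
  cbind(one_in = colSums(A) - colSums(sym),
        one_out = rowSums(A) - rowSums(sym),
        mutual = rowSums(sym))
}
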