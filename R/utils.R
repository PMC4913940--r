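#' Jaccard similarity of two identifier sets
#'
#' The Jaccard index |A intersect B| / |A union B|, used to quantify the
#' overlap between two collections of network identifiers (for example, the
#' networks shared between two published compilations).
#'
#' @param x,y vectors of identifiers (duplicates are ignored).
#' @return A single number in \[0, 1\].
#' @examples
#' jaccard_index(c("a", "b", "c"), c("b", "c", "d"))
#' @export
jaccard_index <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  u <- length(union(x, y))
  if (u == 0L) stop("both sets are empty")
  length(intersect(x, y)) / u
}

#' Percentage of binary networks in a collection
#'
#' Simple utility arithmetic: the percentage k/n * 100 of networks recorded as
#' binary (as opposed to weighted) in a data set of size n.
#'
#' @param n_binary number of binary networks.
#' @param n_total total number of networks.
#' @return Percentage in \[0, 100\].
#' @export
binary_fraction <- function(n_binary, n_total) {
  stopifnot(n_total >= 1, n_binary >= 0, n_binary <= n_total)
  100 * n_binary / n_total
}
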