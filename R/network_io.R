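## Binary ecological networks: bipartite incidence matrices (mutualistic webs)
## and directed adjacency matrices (food webs), plus the site-metadata table
## that carries one row of covariates per network.

#' Construct a bipartite interaction network
#'
#' A binary plant-by-animal incidence matrix with row and column labels.
#' Mutualistic webs (pollination, seed dispersal) are represented this way:
#' links are only drawn between the two parties, and only link presence is
#' recorded.
#'
#' @param incidence numeric matrix of 0/1 entries; rows are plants (or
#'   resources), columns animals (or consumers).
#' @param plant_labels,animal_labels optional identifier vectors; default to
#'   the dimnames of `incidence` or generated labels.
#' @return An object of class `bipartite_network` with elements `incidence`,
#'   `plant_labels`, `animal_labels`.
#' @export
bipartite_network <- function(incidence, plant_labels = NULL,
                              animal_labels = NULL) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "double"
  if (nrow(incidence) < 1L || ncol(incidence) < 1L)
    stop("incidence matrix must have at least one row and one column")
  if (anyNA(incidence) || !all(incidence %in% c(0, 1)))
    stop("incidence entries must all be 0 or 1")
  if (sum(incidence) < 1)
    stop("network has no links (all-zero incidence matrix)")
  plant_labels <- as.character(plant_labels %||% rownames(incidence) %||%
                                 paste0("P", seq_len(nrow(incidence))))
  animal_labels <- as.character(animal_labels %||% colnames(incidence) %||%
                                  paste0("A", seq_len(ncol(incidence))))
  if (length(plant_labels) != nrow(incidence) ||
      length(animal_labels) != ncol(incidence))
    stop("label lengths do not match matrix dimensions")
  if (anyDuplicated(plant_labels) || anyDuplicated(animal_labels))
    stop("duplicate labels within a side are not allowed")
  dimnames(incidence) <- list(plant_labels, animal_labels)
  structure(list(incidence = incidence, plant_labels = plant_labels,
                 animal_labels = animal_labels),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite network: %d plants x %d animals, %d links\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' Construct a directed (food-web) network
#'
#' A binary adjacency matrix over one node set; entry (i, j) = 1 records the
#' directed link i -> j (resource i consumed by j).  Mutual links (both
#' directions present) are allowed; self-links are not.
#'
#' @param adjacency square numeric 0/1 matrix with zero diagonal.
#' @param node_labels optional identifiers; default dimnames or generated.
#' @return An object of class `directed_network`.
#' @export
directed_network <- function(adjacency, node_labels = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("adjacency matrix must be square")
  if (n < 2L) stop("a directed network needs at least 2 nodes")
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1)))
    stop("adjacency entries must all be 0 or 1")
  if (any(diag(adjacency) != 0)) stop("self-edges are not allowed")
  node_labels <- as.character(node_labels %||% rownames(adjacency) %||%
                                paste0("N", seq_len(n)))
  if (length(node_labels) != n) stop("label length does not match matrix")
  if (anyDuplicated(node_labels)) stop("duplicate node labels")
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency, node_labels = node_labels),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  A <- x$adjacency
  mutual <- sum(A * t(A)) / 2
  cat(sprintf("directed network: %d nodes, %d edges (%d mutual pairs)\n",
              nrow(A), sum(A), mutual))
  invisible(x)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a labeled incidence matrix from delimited text
#'
#' Reads a rectangular table (comma- or tab-separated; first row and first
#' column hold labels) and coerces it to a binary incidence matrix: any
#' positive value becomes 1, because only binary structure is analysed.
#' All-zero rows or columns (degree-0 species) are dropped with a warning,
#' since nestedness and the degree-based null model are undefined for them.
#'
#' @param path file path.
#' @param sep field separator; guessed from the first line by default.
#' @return A [bipartite_network].
#' @export
read_incidence_matrix <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  tab <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                    check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("incidence table contains non-numeric entries")
  if (anyNA(m)) stop("incidence table contains missing values")
  if (any(m < 0)) stop("negative entries are not valid interaction records")
  m[m > 0] <- 1
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!any(keep_r) || !any(keep_c)) stop("all-zero incidence matrix")
  if (!all(keep_r) || !all(keep_c)) {
    warning(sprintf("dropped %d all-zero row(s) and %d all-zero column(s)",
                    sum(!keep_r), sum(!keep_c)))
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  bipartite_network(m)
}

#' Write an incidence matrix as delimited text
#'
#' @param net a [bipartite_network].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @export
write_incidence_matrix <- function(net, path, sep = ",") {
  stopifnot(inherits(net, "bipartite_network"))
  df <- data.frame(label = net$plant_labels, net$incidence,
                   check.names = FALSE)
  names(df)[1] <- ""
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed edge list
#'
#' Two-column delimited text of ordered (source, target) pairs; a header line
#' is optional.  Duplicate pairs collapse to a single binary edge; a pair
#' listed in both directions yields a mutual edge.
#'
#' @param path file path.
#' @param sep field separator; guessed by default.
#' @return A [directed_network].
#' @export
read_edge_list <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  tab <- read.table(path, sep = sep, header = FALSE,
                    colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2L) stop("edge list must have two columns")
  tab <- tab[, 1:2]
  if (nrow(tab) > 0 &&
      all(tolower(unlist(tab[1, ])) %in%
            c("source", "target", "from", "to", "resource", "consumer")))
    tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("edge list is empty")
  if (any(tab[[1]] == tab[[2]]))
    stop("self-edges are not allowed (found pair with identical endpoints)")
  nodes <- sort(unique(c(tab[[1]], tab[[2]])))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(match(tab[[1]], nodes), match(tab[[2]], nodes))] <- 1
  directed_network(A, nodes)
}

#' Write a directed network as an edge list
#'
#' @param net a [directed_network].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @export
write_edge_list <- function(net, path, sep = ",") {
  stopifnot(inherits(net, "directed_network"))
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(source = net$node_labels[idx[, 1]],
                   target = net$node_labels[idx[, 2]])
  df <- df[order(df$source, df$target), ]
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a food web to resource-consumer bipartite form
#'
#' Rows are the species that act as resources (out-degree >= 1), columns the
#' species that act as consumers (in-degree >= 1); a species may appear on
#' both sides.  `B[i, j] = 1` iff the directed link i -> j exists.  This is
#' the representation on which NODF is computed for food webs.  Species with
#' no trophic links at all are dropped (they cannot appear on either side).
#'
#' @param net a [directed_network].
#' @return A [bipartite_network]; the link count equals the number of
#'   directed edges of `net`.
#' @export
foodweb_to_bipartite <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  A <- net$adjacency
  if (sum(A) < 1) stop("network has no edges")
  res <- rowSums(A) >= 1
  con <- colSums(A) >= 1
  B <- A[res, con, drop = FALSE]
  bipartite_network(B, net$node_labels[res], net$node_labels[con])
}

## ---- site-metadata tables ---------------------------------------------

site_numeric_cols <- c("latitude", "longitude", "elevation", "T_mean",
                       "T_seasonality", "P_ann", "P_seasonality",
                       "human_impact", "T_velocity", "P_velocity",
                       "n_species", "n_links", "Z_NODF", "Z_M")

## Published-table-style aliases accepted on read.
site_aliases <- list(
  network_id = c("network_id", "network id", "id", "network"),
  network_kind = c("network_kind", "network type", "type", "kind"),
  binary = c("binary", "binary_flag", "network type (binary or weighted)"),
  latitude = c("latitude", "lat"),
  longitude = c("longitude", "lon", "long"),
  elevation = c("elevation", "altitude"),
  T_mean = c("t_mean", "tmean"),
  T_seasonality = c("t_seasonality", "tseasonality"),
  P_ann = c("p_ann", "pann"),
  P_seasonality = c("p_seasonality", "pseasonality"),
  human_impact = c("human_impact", "human impact", "hf", "hf score"),
  T_velocity = c("t_velocity", "tvelocity"),
  P_velocity = c("p_velocity", "pvelocity"),
  n_species = c("n_species", "#species", "species"),
  n_plants = c("n_plants", "#plants", "plants"),
  n_animals = c("n_animals", "#animals", "animals"),
  n_links = c("n_links", "#links", "links"),
  Z_NODF = c("z_nodf", "nodf", "nestedness", "nestedness (standardized nodf)"),
  Z_M = c("z_m", "m", "modularity", "modularity (standardized m)"),
  mainland = c("mainland", "is_mainland")
)

canonicalise_site_names <- function(nms) {
  low <- tolower(trimws(nms))
  out <- nms
  for (canon in names(site_aliases)) {
    hit <- low %in% site_aliases[[canon]]
    out[hit] <- canon
  }
  out
}

validate_site_table <- function(df) {
  problems <- character(0)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
  }
  bad(df$latitude < -90 | df$latitude > 90, "latitude outside [-90, 90]")
  bad(df$longitude < -180 | df$longitude > 180,
      "longitude outside [-180, 180]")
  bad(df$human_impact < 0 | df$human_impact > 100,
      "human_impact outside [0, 100]")
  bad(df$n_links < 1, "n_links must be >= 1")
  bad(df$n_species <= 0, "n_species must be positive")
  bad(df$T_velocity < 0 | df$P_velocity < 0,
      "climate-change velocities must be nonnegative")
  bad(!df$network_kind %in% c("foodweb", "pollination", "seed_dispersal"),
      "network_kind must be foodweb, pollination or seed_dispersal")
  if (length(problems))
    stop("invalid site table:\n  ", paste(problems, collapse = "\n  "))
  invisible(df)
}

#' Read a per-network site-metadata table
#'
#' One row per network: identifier, network kind, coordinates, elevation,
#' climate normals (`T_mean` in 0.1 degC, `T_seasonality` as a standard
#' deviation, `P_ann` in mm, `P_seasonality` as a coefficient of variation),
#' the 0-100 human-footprint score, raw (untransformed) temperature- and
#' precipitation-change velocities, species/link counts and, once computed,
#' the standardized metric scores `Z_NODF` and `Z_M`.  Published-style
#' headers (`#Species`, `#Plants`, `#Animals`, ...) are accepted; when
#' `n_plants`/`n_animals` are supplied instead of `n_species` the species
#' count is derived as their sum.  Invalid rows abort with row-indexed
#' messages.
#'
#' @param path CSV file path.
#' @return A `data.frame` with the canonical columns (class `site_table`).
#' @export
read_site_table <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  names(df) <- canonicalise_site_names(names(df))
  if (!"n_species" %in% names(df) &&
      all(c("n_plants", "n_animals") %in% names(df)))
    df$n_species <- df$n_plants + df$n_animals
  mandatory <- c("network_id", "network_kind", "latitude", "longitude",
                 "elevation", "T_mean", "T_seasonality", "P_ann",
                 "P_seasonality", "human_impact", "T_velocity",
                 "P_velocity", "n_species", "n_links")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("site table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"binary" %in% names(df)) df$binary <- TRUE
  df$binary <- as.logical(df$binary)
  for (cc in intersect(site_numeric_cols, names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  validate_site_table(df)
  class(df) <- c("site_table", "data.frame")
  df
}

#' Write a site-metadata table to CSV
#'
#' Round-trips losslessly with [read_site_table()] at stored precision.
#'
#' @param records a site table `data.frame`.
#' @param path output CSV path.
#' @export
write_site_table <- function(records, path) {
  write.table(as.data.frame(records), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
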