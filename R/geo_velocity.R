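## Climate-change velocity: temporal climate difference (current vs Last
## Glacial Maximum) divided by the local spatial climate gradient.

EARTH_RADIUS_KM <- 6371
KM_PER_DEGREE <- EARTH_RADIUS_KM * pi / 180

#' Gridded climate raster
#'
#' A regular latitude/longitude grid of a climate variable.  `values` is a
#' matrix whose first row is the northernmost row of cells; `origin` is the
#' (latitude, longitude) of the lower-left grid corner; `cell_size` is in
#' decimal degrees.  Missing cells carry `NA`.
#'
#' @param values numeric matrix (>= 3 x 3 for slope computation).
#' @param cell_size cell size in degrees (> 0).
#' @param origin numeric length-2 vector `c(lat, lon)` of the lower-left
#'   corner.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(origin) == 2L)
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  if (nrow(values) < 3L || ncol(values) < 3L)
    stop("raster needs at least 3 x 3 cells for slope computation")
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "raster grid: %d x %d cells of %g deg, lower-left corner (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

## Centre latitude of grid row r (row 1 = northernmost).
cell_lat <- function(raster, row) {
  raster$origin[1] + (nrow(raster$values) - row + 0.5) * raster$cell_size
}

cell_lon <- function(raster, col) {
  raster$origin[2] + (col - 0.5) * raster$cell_size
}

#' Read a plain-text (ESRI ASCII) raster grid
#'
#' Header lines `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value` followed by rows of values, north first.
#'
#' @param path file path.
#' @return A [raster_grid].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("raster header is missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster body does not match ncols * nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_grid(m, hdr$cellsize, c(hdr$yllcorner, hdr$xllcorner))
}

#' Write a raster grid as plain text (ESRI ASCII)
#'
#' @param raster a [raster_grid].
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", raster$origin[2]),
           sprintf("yllcorner %.10g", raster$origin[1]),
           sprintf("cellsize %.10g", raster$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, scientific = FALSE,
                                               trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Local slope of a raster surface from the 4 rook neighbours
#'
#' Central differences against the east/west and north/south neighbours:
#' `dz/dx = (east - west) / (2 dx)`, `dz/dy = (north - south) / (2 dy)`,
#' slope = sqrt((dz/dx)^2 + (dz/dy)^2), with dx and dy the great-circle cell
#' spacings in km at the cell's latitude (spherical Earth, radius 6371 km).
#'
#' @param raster a [raster_grid].
#' @param row,col cell indices (row 1 = northernmost).
#' @return Slope in variable units per km; `NA` with a warning for edge
#'   cells or cells with a missing neighbour.
#' @export
local_slope_4n <- function(raster, row, col) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  if (row <= 1L || row >= nrow(v) || col <= 1L || col >= ncol(v)) {
    warning("slope undefined at edge cell (", row, ", ", col, ")")
    return(NA_real_)
  }
  north <- v[row - 1L, col]
  south <- v[row + 1L, col]
  east <- v[row, col + 1L]
  west <- v[row, col - 1L]
  if (anyNA(c(north, south, east, west, v[row, col]))) {
    warning("slope undefined: missing neighbour at (", row, ", ", col, ")")
    return(NA_real_)
  }
  dy_km <- KM_PER_DEGREE * raster$cell_size
  dx_km <- KM_PER_DEGREE * cos(cell_lat(raster, row) * pi / 180) *
    raster$cell_size
  sqrt(((east - west) / (2 * dx_km))^2 + ((north - south) / (2 * dy_km))^2)
}

locate_cell <- function(raster, lat, lon) {
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  col <- floor((lon - raster$origin[2]) / raster$cell_size) + 1
  row_from_bottom <- floor((lat - raster$origin[1]) / raster$cell_size)
  row <- nr - row_from_bottom
  if (row < 1 || row > nr || col < 1 || col > nc)
    stop(sprintf("site (%g, %g) lies outside the raster grid", lat, lon))
  c(row = as.integer(row), col = as.integer(col))
}

#' Climate-change velocity at a site
#'
#' Velocity = temporal gradient / spatial gradient: the temporal gradient is
#' the absolute difference between current and Last Glacial Maximum (LGM)
#' conditions at the site's grid cell, and the spatial gradient is the local
#' slope of the *current* climate surface there ([local_slope_4n()]).  Sites
#' on a locally flat current surface (zero slope) get an undefined velocity
#' rather than a fabricated floor value.
#'
#' @param current,lgm aligned [raster_grid]s of the same variable.
#' @param lat,lon site coordinates in decimal degrees.
#' @param eps offset added inside the log (see [log_transform()]).
#' @return A list with `temporal_gradient`, `spatial_gradient`, `velocity`
#'   (km per unit time-normalised ratio), `log_velocity`, and `defined`.
#' @export
climate_velocity <- function(current, lgm, lat, lon, eps = 1e-6) {
  stopifnot(inherits(current, "raster_grid"), inherits(lgm, "raster_grid"))
  if (!identical(dim(current$values), dim(lgm$values)) ||
      current$cell_size != lgm$cell_size ||
      !isTRUE(all.equal(current$origin, lgm$origin)))
    stop("current and LGM rasters are not aligned")
  cell <- locate_cell(current, lat, lon)
  cur <- current$values[cell[["row"]], cell[["col"]]]
  old <- lgm$values[cell[["row"]], cell[["col"]]]
  if (anyNA(c(cur, old)))
    stop("missing climate value at the site's grid cell")
  temporal <- abs(cur - old)
  spatial <- unname(local_slope_4n(current, cell[["row"]], cell[["col"]]))
  defined <- !is.na(spatial) && spatial > 0
  velocity <- if (defined) temporal / spatial else NA_real_
  list(temporal_gradient = temporal, spatial_gradient = spatial,
       velocity = velocity,
       log_velocity = if (defined) log(velocity + eps) else NA_real_,
       defined = defined)
}

#' Offset log transform for climate-change velocities
#'
#' Velocities enter all regressions on the natural-log scale.  Because a
#' velocity can be exactly zero, a small offset is added before taking logs:
#' by default 1e-6 times the smallest positive value, so the transform is an
#' epsilon-perturbation of the plain log for strictly positive data.
#'
#' @param values nonnegative numeric vector.
#' @param eps offset; default `1e-6 * min(values[values > 0])`.
#' @return `log(values + eps)`.
#' @export
log_transform <- function(values, eps = NULL) {
  if (any(values < 0, na.rm = TRUE))
    stop("velocities must be nonnegative")
  if (is.null(eps)) {
    pos <- values[!is.na(values) & values > 0]
    if (!length(pos))
      stop("cannot choose a log offset: no positive values")
    eps <- 1e-6 * min(pos)
  }
  log(values + eps)
}
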