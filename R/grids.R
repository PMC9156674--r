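# Gridded-data plumbing: cell-center coordinates, polygon rasterization by the
# center-point rule, and plain-text ESRI ASCII grid I/O.
#
# Convention: grids are row-major matrices with row 1 at the top (north) edge;
# the map coordinate of cell (i, j) center is
#   x = xll + (j - 0.5) * cell_size,  y = yll + (nrow - i + 0.5) * cell_size.

#' Cell-center coordinates of a grid
#'
#' @param nrow,ncol grid dimensions.
#' @param cell_size cell edge length (m).
#' @param xll,yll map coordinates of the lower-left corner of the grid.
#' @return list with matrices `x` and `y` of cell-center coordinates.
#' @export
cell_centers <- function(nrow, ncol, cell_size, xll = 0, yll = 0) {
  x <- xll + (seq_len(ncol) - 0.5) * cell_size
  y <- yll + (nrow - seq_len(nrow) + 0.5) * cell_size
  list(
    x = matrix(x, nrow = nrow, ncol = ncol, byrow = TRUE),
    y = matrix(y, nrow = nrow, ncol = ncol)
  )
}

#' Rasterize a polygon by the center-point rule
#'
#' A cell is inside the polygon iff its center falls inside (or on the
#' boundary of) the polygon.
#'
#' @param poly two-column matrix or data frame of polygon vertex coordinates
#'   (x, y), in map units; the ring need not be closed.
#' @param nrow,ncol grid dimensions.
#' @param cell_size cell edge length (m).
#' @param xll,yll lower-left corner of the grid.
#' @return logical matrix, `TRUE` inside the polygon.
#' @export
rasterize_polygon <- function(poly, nrow, ncol, cell_size, xll = 0, yll = 0) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) {
    stop("`poly` must be a two-column matrix with at least 3 vertices", call. = FALSE)
  }
  cc <- cell_centers(nrow, ncol, cell_size, xll, yll)
  inside <- pracma::inpolygon(as.vector(cc$x), as.vector(cc$y),
                              poly[, 1], poly[, 2], boundary = TRUE)
  matrix(inside, nrow = nrow, ncol = ncol)
}

#' Circular fire footprint polygon
#'
#' Convenience constructor for disc-shaped burn footprints.
#'
#' @param cx,cy center (map units).
#' @param radius radius (map units).
#' @param n number of vertices.
#' @return two-column matrix of vertex coordinates.
#' @export
disc_footprint <- function(cx, cy, radius, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + radius * cos(th), y = cy + radius * sin(th))
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text interchange for single grids (burn masks, time-since-fire,
#' anomalies). `NA` cells are written as the nodata value.
#'
#' @param grid numeric or logical matrix.
#' @param path output file.
#' @param cell_size cell edge length (m).
#' @param xll,yll lower-left corner.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, cell_size, xll = 0, yll = 0,
                             nodata = -9999) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  grid[is.na(grid)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(grid)),
    sprintf("nrows %d", nrow(grid)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(grid, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any conforming source.
#' @return numeric matrix with attributes `cell_size`, `xll`, `yll`; nodata
#'   cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2])
  names(vals) <- tolower(kv[, 1])
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (nrow(m) != vals[["nrows"]] || ncol(m) != vals[["ncols"]]) {
    stop("ASCII grid body does not match its header dimensions", call. = FALSE)
  }
  m[m == vals[["nodata_value"]]] <- NA_real_
  attr(m, "cell_size") <- vals[["cellsize"]]
  attr(m, "xll") <- vals[["xllcorner"]]
  attr(m, "yll") <- vals[["yllcorner"]]
  m
}
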