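#' Regular raster grid on a planar window
#'
#' A minimal matrix-backed container for gridded surfaces (population,
#' sealing, density, z, p). Values are stored row-major from the *top* row of
#' the grid; the window is `[xmin, xmin + ncol * cellsize] x
#' [ymin, ymin + nrow * cellsize]` in metres. Cells are half-open:
#' `[x, x + cellsize) x [y - cellsize, y)` measured from a cell's left/top
#' edges, so every interior point belongs to exactly one cell.
#'
#' @param values Numeric matrix, `nrow` rows by `ncol` columns, row 1 at the
#'   top (largest y).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid (metres).
#' @param cellsize Cell edge length (metres).
#' @return An object of class `rr_raster`.
#' @export
rr_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "rr_raster"
  )
}

#' @export
print.rr_raster <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf(
    "<rr_raster> %d x %d cells of %g m; window [%g, %g] x [%g, %g]; values in [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, raster_xmax(x), x$ymin, raster_ymax(x), rng[1], rng[2]
  ))
  invisible(x)
}

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$cellsize
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$cellsize

#' @export
dim.rr_raster <- function(x) dim(x$values)

#' Cell geometry helpers
#'
#' `raster_x_centers()`/`raster_y_centers()` return the coordinates of cell
#' centres (y descending, matching the row order); `raster_cell_area()` the
#' area of one cell in square metres; `raster_window()` the window as
#' `c(xmin, xmax, ymin, ymax)`.
#'
#' @param r An `rr_raster`.
#' @name raster-geometry
#' @export
raster_x_centers <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

#' @rdname raster-geometry
#' @export
raster_y_centers <- function(r) raster_ymax(r) - (seq_len(nrow(r$values)) - 0.5) * r$cellsize

#' @rdname raster-geometry
#' @export
raster_cell_area <- function(r) r$cellsize^2

#' @rdname raster-geometry
#' @export
raster_window <- function(r) c(r$xmin, raster_xmax(r), r$ymin, raster_ymax(r))

#' Blank raster covering a window
#'
#' @param window Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param cellsize Cell edge (metres); the window extent must be (close to) a
#'   multiple of it.
#' @param fill Initial cell value.
#' @return An `rr_raster`.
#' @export
raster_template <- function(window, cellsize, fill = 0) {
  nx <- round((window[2] - window[1]) / cellsize)
  ny <- round((window[4] - window[3]) / cellsize)
  stopifnot(nx >= 1, ny >= 1)
  if (abs(nx * cellsize - (window[2] - window[1])) > 1e-6 * cellsize ||
      abs(ny * cellsize - (window[4] - window[3])) > 1e-6 * cellsize) {
    stop("window extent is not a multiple of `cellsize`", call. = FALSE)
  }
  rr_raster(matrix(fill, nrow = ny, ncol = nx),
            xmin = window[1], ymin = window[3], cellsize = cellsize)
}

#' Locate points on the grid
#'
#' Maps coordinates to (row, column) indices under the half-open cell
#' convention; points on the top or right window edge are clamped into the
#' outermost cells so that every point of the closed window has a cell.
#'
#' @param r An `rr_raster`.
#' @param x,y Coordinate vectors (metres).
#' @return A list with integer vectors `row`, `col` and `cell` (column-major
#'   linear index into `r$values`).
#' @export
raster_cell_index <- function(r, x, y) {
  nx <- ncol(r$values); ny <- nrow(r$values)
  col <- pmin(pmax(floor((x - r$xmin) / r$cellsize) + 1L, 1L), nx)
  row <- pmin(pmax(ceiling((raster_ymax(r) - y) / r$cellsize), 1L), ny)
  list(row = as.integer(row), col = as.integer(col),
       cell = as.integer((col - 1L) * ny + row))
}

#' Look up raster values at point locations
#'
#' @inheritParams raster_cell_index
#' @return Numeric vector of the values of the cells containing each point.
#' @export
raster_value_at <- function(r, x, y) {
  idx <- raster_cell_index(r, x, y)
  r$values[cbind(idx$row, idx$col)]
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Long-format view of a raster
#'
#' @param x An `rr_raster`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (cell centres) and `value`.
#' @export
as_tibble.rr_raster <- function(x, ...) {
  xs <- rep(raster_x_centers(x), each = nrow(x$values))
  ys <- rep(raster_y_centers(x), times = ncol(x$values))
  vs <- as.vector(x$values)
  tibble::tibble(x = xs, y = ys, value = vs)
}

#' @export
autoplot.rr_raster <- function(object, ...) {
  df <- as_tibble.rr_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x [m]", y = "y [m]")
}
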