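#' Edge-correction factor for a Gaussian kernel in a rectangular window
#'
#' Mass of the radially symmetric bivariate Gaussian kernel with bandwidth `h`
#' centred at `(x, y)` that falls inside the window — the product of two
#' univariate normal interval probabilities. Kernel contributions are divided
#' by this factor (Diggle's correction, evaluated at each data point; the
#' adaptive variant uses each point's own bandwidth), which restores unit mass
#' of the corrected density inside the window.
#'
#' @param x,y Coordinates (vectors, metres).
#' @param h Bandwidth(s), recycled against `x`.
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @return Factor(s) in (0, 1], clamped below at 1e-12.
#' @export
edge_correct_factor <- function(x, y, h, window) {
  check_window(window)
  fx <- stats::pnorm((window[2] - x) / h) - stats::pnorm((window[1] - x) / h)
  fy <- stats::pnorm((window[4] - y) / h) - stats::pnorm((window[3] - y) / h)
  pmax(fx * fy, 1e-12)
}

# kernel sum over the grid; h is scalar or per-point; exploits the
# separability of the Gaussian kernel: one outer product per point.
kde_accumulate <- function(x, y, h, wt, grid) {
  xc <- raster_x_centers(grid)
  yc <- raster_y_centers(grid)
  acc <- matrix(0, nrow = nrow(grid$values), ncol = ncol(grid$values))
  h <- rep_len(h, length(x))
  for (i in seq_along(x)) {
    kx <- stats::dnorm(xc, mean = x[i], sd = h[i])
    ky <- stats::dnorm(yc, mean = y[i], sd = h[i])
    acc <- acc + wt[i] * (ky %o% kx)
  }
  acc
}

new_density_surface <- function(raster, pattern_n, edge_correction, h = NULL,
                                per_point_h = NULL, points = NULL) {
  structure(
    list(raster = raster, pattern_n = pattern_n, kernel = "gaussian",
         edge_correction = edge_correction, h = h,
         per_point_h = per_point_h, points = points),
    class = "rr_density"
  )
}

#' @export
print.rr_density <- function(x, ...) {
  bw <- if (!is.null(x$h)) sprintf("fixed h = %.2f m", x$h)
        else sprintf("adaptive h_i in [%.2f, %.2f] m", min(x$per_point_h), max(x$per_point_h))
  cat(sprintf("<rr_density> n = %d, %s, edge correction: %s\n",
              x$pattern_n, bw, x$edge_correction))
  invisible(x)
}

#' Fixed-bandwidth bivariate Gaussian kernel density estimate
#'
#' `fhat(x) = (1/n) sum_i h^-2 K((x - X_i)/h)` evaluated at the cell centres
#' of the analysis grid, with K the radially symmetric bivariate Gaussian.
#' With Diggle's correction each point's kernel is divided by its mass inside
#' the window, so the corrected estimate integrates to 1 over the window (up
#' to grid discretisation).
#'
#' @param pattern Point pattern (data frame with `x`, `y`).
#' @param h Bandwidth (metres, > 0).
#' @param grid [rr_raster] template for the evaluation grid; must cover all
#'   points.
#' @param edge_correction `"diggle"` (default) or `"none"`.
#' @return An `rr_density` object; `$raster` holds the density per m2.
#' @export
fixed_kde <- function(pattern, h, grid, edge_correction = c("diggle", "none")) {
  edge_correction <- match.arg(edge_correction)
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be a positive scalar", call. = FALSE)
  adaptive_kde(pattern, rep(h, nrow(pattern)), grid,
               edge_correction = edge_correction, .fixed_h = h)
}

#' Adaptive (per-point bandwidth) kernel density estimate
#'
#' Sum of per-point Gaussian kernels, each with its own bandwidth `h_i`
#' (Abramson scheme: see [adaptive_bandwidths()]). With all `h_i` equal this
#' reduces exactly to [fixed_kde()]. Edge correction divides each kernel by
#' its own in-window mass.
#'
#' @param pattern Point pattern (data frame with `x`, `y`).
#' @param per_point_h Vector of bandwidths, one per point (metres, > 0).
#' @param grid [rr_raster] evaluation grid covering all points.
#' @param edge_correction `"diggle"` (default) or `"none"`.
#' @param .fixed_h Internal: records a common bandwidth on the result.
#' @return An `rr_density` object.
#' @export
adaptive_kde <- function(pattern, per_point_h, grid,
                         edge_correction = c("diggle", "none"), .fixed_h = NULL) {
  edge_correction <- match.arg(edge_correction)
  x <- pattern$x; y <- pattern$y
  n <- length(x)
  if (length(per_point_h) != n) {
    stop("length mismatch between points and bandwidths", call. = FALSE)
  }
  if (any(per_point_h <= 0)) stop("all bandwidths must be > 0", call. = FALSE)
  window <- raster_window(grid)
  if (any(x < window[1] | x > window[2] | y < window[3] | y > window[4])) {
    stop("grid does not cover all points", call. = FALSE)
  }
  wt <- rep(1 / n, n)
  if (edge_correction == "diggle") {
    wt <- wt / edge_correct_factor(x, y, per_point_h, window)
  }
  vals <- kde_accumulate(x, y, per_point_h, wt, grid)
  out <- rr_raster(vals, xmin = grid$xmin, ymin = grid$ymin, cellsize = grid$cellsize)
  new_density_surface(out, n, edge_correction,
                      h = .fixed_h, per_point_h = per_point_h,
                      points = tibble::tibble(x = x, y = y))
}

#' Evaluate a fixed-bandwidth KDE at arbitrary points
#'
#' Exact (non-gridded) evaluation; used for pilot densities at the data
#' points.
#'
#' @param pattern Source point pattern.
#' @param h Bandwidth (metres).
#' @param at Data frame with `x`, `y` where the density is evaluated.
#' @param window Window for edge correction (default: the pattern's).
#' @param edge_correction `"diggle"` or `"none"`.
#' @return Numeric vector of densities per m2.
#' @export
kde_at_points <- function(pattern, h, at, window = NULL,
                          edge_correction = c("diggle", "none")) {
  edge_correction <- match.arg(edge_correction)
  window <- pattern_window(pattern, window)
  x <- pattern$x; y <- pattern$y
  n <- length(x)
  wt <- rep(1 / n, n)
  if (edge_correction == "diggle") {
    wt <- wt / edge_correct_factor(x, y, h, window)
  }
  vapply(seq_len(nrow(at)), function(j) {
    d2 <- (at$x[j] - x)^2 + (at$y[j] - y)^2
    sum(wt * exp(-d2 / (2 * h^2))) / (2 * pi * h^2)
  }, numeric(1))
}

#' Abramson adaptive per-point bandwidths
#'
#' `h_i = h0 * f(X_i)^(-1/2) / gamma`, where `f` is a pilot density estimate
#' and `gamma` the geometric mean of the `f(X_i)^(-1/2)` terms, so that the
#' geometric mean of the returned bandwidths equals the global bandwidth `h0`
#' exactly. Points in dense (urban) regions receive small bandwidths, points
#' in sparse (rural) regions large ones.
#'
#' @param pattern Point pattern (data frame with `x`, `y`).
#' @param pilot_density Pilot density at the data points: a numeric vector, an
#'   `rr_density`, or an [rr_raster] (looked up at the points).
#' @param h0 Global bandwidth (metres, > 0).
#' @param floor Lower clip for the pilot density (per m2) guarding against
#'   infinite bandwidths at stray points; clipping is reported via a warning.
#' @return Numeric vector of per-point bandwidths (metres).
#' @export
adaptive_bandwidths <- function(pattern, pilot_density, h0, floor = 1e-12) {
  stopifnot(h0 > 0)
  f <- if (is.numeric(pilot_density)) {
    pilot_density
  } else if (inherits(pilot_density, "rr_density")) {
    raster_value_at(pilot_density$raster, pattern$x, pattern$y)
  } else if (inherits(pilot_density, "rr_raster")) {
    raster_value_at(pilot_density, pattern$x, pattern$y)
  } else {
    stop("unsupported pilot_density", call. = FALSE)
  }
  if (length(f) != nrow(pattern)) {
    stop("pilot density length does not match the pattern", call. = FALSE)
  }
  if (any(f <= 0)) {
    bad <- sum(f <= 0)
    if (any(f < 0)) stop("negative pilot density", call. = FALSE)
    warning(sprintf("pilot density floored at %g per m2 for %d point(s)", floor, bad),
            call. = FALSE)
  }
  f <- pmax(f, floor)
  s <- f^(-0.5)
  gamma <- exp(mean(log(s)))
  h0 * s / gamma
}

#' Riemann-sum integral of a density surface over its window
#'
#' @param density An `rr_density` or [rr_raster].
#' @return The integral (dimensionless; ~1 for an edge-corrected KDE).
#' @export
density_integral <- function(density) {
  r <- if (inherits(density, "rr_density")) density$raster else density
  sum(r$values) * raster_cell_area(r)
}

#' @export
autoplot.rr_density <- function(object, ...) {
  autoplot.rr_raster(object$raster) +
    ggplot2::labs(fill = "density [1/m\u00b2]")
}
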