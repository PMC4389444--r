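# density floor (per m2) applied before the ratio; cells where BOTH densities
# sit at the floor carry no information and are masked from testing
RR_DENSITY_FLOOR <- 1e-12

#' Log spatial relative risk surface
#'
#' Cellwise `log(fhat(x) / ghat(x))` of the case and control density surfaces.
#' Both densities are floored at a small constant before division; cells where
#' both sit at the floor (no case and no control mass) are recorded in the
#' `masked` attribute and excluded from testing downstream.
#'
#' @param f_surface,g_surface Case / control `rr_density` (or [rr_raster]) on
#'   the same grid.
#' @param floor Density floor (per m2).
#' @return An [rr_raster] of log relative risk with attribute `masked`
#'   (logical matrix).
#' @export
log_relative_risk <- function(f_surface, g_surface, floor = RR_DENSITY_FLOOR) {
  f <- if (inherits(f_surface, "rr_density")) f_surface$raster else f_surface
  g <- if (inherits(g_surface, "rr_density")) g_surface$raster else g_surface
  stopifnot_same_grid(f, g)
  fv <- pmax(f$values, floor)
  gv <- pmax(g$values, floor)
  out <- rr_raster(log(fv / gv), xmin = f$xmin, ymin = f$ymin, cellsize = f$cellsize)
  attr(out, "masked") <- (f$values <= floor) & (g$values <= floor)
  out
}

# local bandwidth surface for the adaptive variance: inverse-distance-weighted
# h_i over the k nearest sample points, evaluated at cell centres
local_bandwidth_surface <- function(points, per_point_h, grid, k = 8) {
  xc <- raster_x_centers(grid); yc <- raster_y_centers(grid)
  ny <- length(yc); nx <- length(xc)
  k <- min(k, length(per_point_h))
  px <- points$x; py <- points$y
  out <- matrix(0, nrow = ny, ncol = nx)
  for (j in seq_len(nx)) {
    dx2 <- (px - xc[j])^2
    for (i in seq_len(ny)) {
      d2 <- dx2 + (py - yc[i])^2
      nn <- order(d2)[seq_len(k)]
      w <- 1 / pmax(d2[nn], 1e-6)
      out[i, j] <- sum(w * per_point_h[nn]) / sum(w)
    }
  }
  out
}

#' Asymptotic z-statistic surface for the log relative risk
#'
#' Pointwise test of H0: r(x) = 0 against H1: r(x) > 0 via the plug-in
#' asymptotic variance of the log relative risk,
#' `V(x) = R(K) * (1/(n_f h_f(x)^2 fhat(x)) + 1/(n_g h_g(x)^2 ghat(x)))` with
#' `R(K) = 1/(4 pi)` for the bivariate Gaussian kernel, and
#' `z(x) = log-RR(x) / sqrt(V(x)) ~ N(0, 1)` under H0. The fixed estimator
#' uses `h_f = h_g = h_fixed`; the adaptive estimator uses local bandwidth
#' surfaces interpolated from the per-point bandwidths (inverse-distance
#' weighting over the 8 nearest sample points). Cells masked in the log-RR
#' surface are returned as `NA`.
#'
#' @param log_rr Log relative-risk raster from [log_relative_risk()].
#' @param f_surface,g_surface The `rr_density` objects used for `log_rr`
#'   (must carry their bandwidth metadata).
#' @param n_f,n_g Case/control sample sizes; default: taken from the surfaces.
#' @return An [rr_raster] of z values (NA on masked cells).
#' @export
asymptotic_z <- function(log_rr, f_surface, g_surface,
                         n_f = f_surface$pattern_n, n_g = g_surface$pattern_n) {
  stopifnot(inherits(f_surface, "rr_density"), inherits(g_surface, "rr_density"))
  stopifnot_same_grid(f_surface$raster, g_surface$raster)
  stopifnot_same_grid(log_rr, f_surface$raster)
  grid <- f_surface$raster
  h2_of <- function(s) {
    if (!is.null(s$h)) {
      s$h^2
    } else {
      local_bandwidth_surface(s$points, s$per_point_h, grid)^2
    }
  }
  fv <- pmax(f_surface$raster$values, RR_DENSITY_FLOOR)
  gv <- pmax(g_surface$raster$values, RR_DENSITY_FLOOR)
  v <- (1 / (4 * pi)) * (1 / (n_f * h2_of(f_surface) * fv) +
                           1 / (n_g * h2_of(g_surface) * gv))
  z <- log_rr$values / sqrt(v)
  masked <- attr(log_rr, "masked")
  if (!is.null(masked)) z[masked] <- NA_real_
  rr_raster(z, xmin = grid$xmin, ymin = grid$ymin, cellsize = grid$cellsize)
}

#' One-sided p-value surface
#'
#' Upper-tail p-values `P(Z > z(x))` for the elevated-risk alternative.
#'
#' @param z [rr_raster] of z values.
#' @return [rr_raster] of p values in (0, 1]; NA cells propagate.
#' @export
p_surface <- function(z) {
  rr_raster(stats::pnorm(z$values, lower.tail = FALSE),
            xmin = z$xmin, ymin = z$ymin, cellsize = z$cellsize)
}

#' Significance tolerance contours
#'
#' Extracts the significant region `{x : p(x) < alpha}` of the one-sided
#' p-value surface: as a boolean raster mask (cell-centre rule, used for all
#' area overlays) and as iso-lines of p at level `alpha` traced on the cell
#' centres (marching-squares, via [grDevices::contourLines()]). NA cells count
#' as not significant.
#'
#' @param p [rr_raster] of one-sided p values.
#' @param alpha Significance level in (0, 1]; `alpha = 1` is a degenerate
#'   sentinel selecting the whole window.
#' @return An object of class `rr_contours`: list with `mask` (0/1
#'   [rr_raster]), `polygons` (tibble `ring`, `x`, `y`), `alpha` and
#'   `significant_area_m2`.
#' @export
tolerance_contours <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  pv <- p$values
  sig <- if (alpha >= 1) {
    matrix(TRUE, nrow = nrow(pv), ncol = ncol(pv)) # whole-window sentinel
  } else {
    !is.na(pv) & pv < alpha
  }
  mask <- rr_raster(sig * 1, xmin = p$xmin, ymin = p$ymin, cellsize = p$cellsize)
  polys <- tibble::tibble(ring = integer(), x = numeric(), y = numeric())
  if (alpha < 1 && any(sig) && !all(sig)) {
    xc <- raster_x_centers(p)
    yc <- raster_y_centers(p)
    zmat <- pv
    zmat[is.na(zmat)] <- 1
    # contourLines wants ascending x (rows of its matrix) and y (cols):
    # transpose so dim 1 runs over x, and flip y to ascending
    m <- t(zmat)[, rev(seq_along(yc)), drop = FALSE]
    cl <- grDevices::contourLines(x = xc, y = rev(yc), z = m, levels = alpha)
    if (length(cl) > 0) {
      polys <- purrr::imap_dfr(cl, function(ln, i) {
        tibble::tibble(ring = i, x = ln$x, y = ln$y)
      })
    }
  }
  structure(
    list(mask = mask, polygons = polys, alpha = alpha,
         significant_area_m2 = sum(mask$values) * raster_cell_area(mask)),
    class = "rr_contours"
  )
}

#' Shoelace areas of contour rings
#'
#' @param contours An `rr_contours` object.
#' @return Tibble with `ring` and `area_m2` (absolute shoelace area).
#' @export
contour_ring_areas <- function(contours) {
  if (nrow(contours$polygons) == 0) {
    return(tibble::tibble(ring = integer(), area_m2 = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(contours$polygons, .data$ring),
    area_m2 = abs(sum(.data$x * dplyr::lead(.data$y, default = dplyr::first(.data$y)) -
                        dplyr::lead(.data$x, default = dplyr::first(.data$x)) * .data$y)) / 2,
    .groups = "drop"
  )
}

#' Spatial relative risk surface for one estimator
#'
#' Runs one full estimator: case and control KDEs (fixed bandwidth, or
#' adaptive with LSCV pilots and global bandwidth `h0`), log relative risk,
#' asymptotic z and one-sided p surfaces, and the significance tolerance
#' contours at `alpha`.
#'
#' @param cases,controls Point patterns (tibbles with `x`, `y`).
#' @param spec A [bandwidth_spec()]; the adaptive estimator requires pilots.
#' @param grid [rr_raster] analysis-grid template.
#' @param estimator `"fixed"` or `"adaptive"`.
#' @param alpha Significance level for the tolerance contours.
#' @param edge_correction `"diggle"` or `"none"`.
#' @return An object of class `rr_risk_surface`: list with `log_rr`, `z`, `p`
#'   rasters, `contours` (`rr_contours`), densities `f` and `g`, `estimator`,
#'   `spec`, `alpha`, `n_f`, `n_g`.
#' @export
risk_surface <- function(cases, controls, spec, grid,
                         estimator = c("fixed", "adaptive"), alpha = 0.05,
                         edge_correction = "diggle") {
  estimator <- match.arg(estimator)
  window <- raster_window(grid)
  if (estimator == "fixed") {
    f <- fixed_kde(cases, spec$h_fixed, grid, edge_correction)
    g <- fixed_kde(controls, spec$h_fixed, grid, edge_correction)
  } else {
    if (is.null(spec$h_pilot_f) || is.null(spec$h_pilot_g)) {
      stop("adaptive estimator needs pilot bandwidths in the spec", call. = FALSE)
    }
    pf <- kde_at_points(cases, spec$h_pilot_f, cases, window = window,
                        edge_correction = edge_correction)
    pg <- kde_at_points(controls, spec$h_pilot_g, controls, window = window,
                        edge_correction = edge_correction)
    hf <- adaptive_bandwidths(cases, pf, spec$h0_global)
    hg <- adaptive_bandwidths(controls, pg, spec$h0_global)
    f <- adaptive_kde(cases, hf, grid, edge_correction)
    g <- adaptive_kde(controls, hg, grid, edge_correction)
  }
  lrr <- log_relative_risk(f, g)
  z <- asymptotic_z(lrr, f, g)
  p <- p_surface(z)
  structure(
    list(log_rr = lrr, z = z, p = p, contours = tolerance_contours(p, alpha),
         f = f, g = g, estimator = estimator, spec = spec, alpha = alpha,
         n_f = nrow(cases), n_g = nrow(controls)),
    class = "rr_risk_surface"
  )
}

#' @export
print.rr_risk_surface <- function(x, ...) {
  cat(sprintf(
    "<rr_risk_surface> %s estimator (scenario %s); n_f = %d, n_g = %d; %.2f km2 significant at alpha = %g\n",
    x$estimator, x$spec$scenario, x$n_f, x$n_g,
    x$contours$significant_area_m2 / 1e6, x$alpha
  ))
  invisible(x)
}

#' @export
tidy.rr_risk_surface <- function(x, ...) {
  df <- as_tibble.rr_raster(x$log_rr)
  names(df)[3] <- "log_rr"
  df$z <- as.vector(x$z$values)
  df$p <- as.vector(x$p$values)
  df$significant <- as.vector(x$contours$mask$values) > 0
  df
}

#' @export
glance.rr_risk_surface <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator, scenario = x$spec$scenario, alpha = x$alpha,
    n_f = x$n_f, n_g = x$n_g,
    h_fixed = x$spec$h_fixed, h0_global = x$spec$h0_global,
    significant_area_m2 = x$contours$significant_area_m2
  )
}

#' @export
autoplot.rr_risk_surface <- function(object, ...) {
  df <- tidy.rr_risk_surface(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$log_rr)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [m]", y = "y [m]", fill = "log RR",
                  title = sprintf("%s estimator", object$estimator))
  if (nrow(object$contours$polygons) > 0) {
    gg <- gg + ggplot2::geom_path(
      data = object$contours$polygons,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$ring),
      colour = "black"
    )
  }
  gg
}

#' Write the significant regions as GeoJSON
#'
#' Contour rings become Polygon features with properties `alpha`, `estimator`
#' and `scenario`.
#'
#' @param surface An `rr_risk_surface`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(surface, path) {
  polys <- surface$contours$polygons
  feats <- if (nrow(polys) == 0) list() else {
    lapply(split(polys, polys$ring), function(rg) {
      ring <- c(purrr::map2(rg$x, rg$y, c), list(c(rg$x[1], rg$y[1])))
      list(
        type = "Feature",
        properties = list(alpha = surface$alpha, estimator = surface$estimator,
                          scenario = surface$spec$scenario),
        geometry = list(type = "Polygon", coordinates = list(ring))
      )
    })
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(feats)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
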