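#' Configuration of the synthetic study region
#'
#' The generator emulates a registry-style study area: a rectangular window
#' with a rural background and a few compact urban cores, a surface-sealing
#' (imperviousness) raster in percent, an unobserved building-height
#' multiplier concentrated in the cores, a community partition carrying the
#' population counts available to the disaggregation, and a finer census-tract
#' partition carrying the reference counts used to measure the disaggregation
#' error. Population is disaggregated onto a fine grid proportionally to
#' sealing alone; because true population also scales with building height,
#' urban tracts come out underestimated (negative relative error) and become
#' the known "risk areas".
#'
#' @param window_size Side length of the square window (metres).
#' @param pop_cellsize Population grid cell (metres).
#' @param analysis_cellsize Analysis/KDE grid cell (metres).
#' @param n_communities Communities per side (window is split into an
#'   `n_communities x n_communities` partition).
#' @param tracts_per_community Tracts per side within one community.
#' @param n_cores Number of urban cores.
#' @param core_radius Gaussian radius of a core (metres).
#' @param core_sealing Peak sealing added by a core (percent).
#' @param n_towns Number of secondary towns/villages (sealed but single-story:
#'   they cluster the settlement pattern without contributing height bias).
#' @param town_radius Range `c(min, max)` of town Gaussian radii (metres).
#' @param town_sealing Peak sealing added by a town (percent).
#' @param rural_sealing Mean rural background sealing (percent).
#' @param rural_sealing_sdlog Log-scale sd of the rural sealing noise.
#' @param height_max Peak building-height multiplier in core centres (>= 1).
#' @param total_population Total persons in the window.
#' @param community_noise_sdlog Log-scale sd of community-count noise around
#'   proportionality to built mass.
#' @return A list of class `region_config`.
#' @export
region_config <- function(window_size = 19200,
                          pop_cellsize = 20,
                          analysis_cellsize = 200,
                          n_communities = 6,
                          tracts_per_community = 4,
                          n_cores = 3,
                          core_radius = 500,
                          core_sealing = 40,
                          n_towns = 40,
                          town_radius = c(150, 350),
                          town_sealing = 35,
                          rural_sealing = 2,
                          rural_sealing_sdlog = 0.5,
                          height_max = 6,
                          total_population = 2e5,
                          community_noise_sdlog = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$height_max >= 1, cfg$n_cores >= 0, cfg$total_population > 0)
  tract_size <- window_size / n_communities / tracts_per_community
  rem <- tract_size %% pop_cellsize
  if (min(rem, pop_cellsize - rem) > 1e-9) {
    stop("tract size must be a multiple of the population cell size", call. = FALSE)
  }
  structure(cfg, class = "region_config")
}

#' Generate a synthetic study region
#'
#' Builds the sealing and height rasters, the community and tract partitions
#' with their true counts, the true population grid (sealing x height) and the
#' biased dasymetric estimate (sealing only), and the tract-level relative
#' errors of the estimate.
#'
#' @param config A [region_config()].
#' @param seed Optional integer seed (sets the RNG before generation).
#' @return An object of class `rr_region`: a list with elements `window`,
#'   `config`, `seed`, `sealing`, `height_factor`, `true_population`,
#'   `biased_estimate` (all [rr_raster]s at `pop_cellsize`), `communities` and
#'   `tracts` (tibbles), and `cores` (tibble of core centres/radii).
#' @export
simulate_region <- function(config = region_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- config$window_size
  window <- c(0, w, 0, w)
  cs <- config$pop_cellsize

  sealing <- raster_template(window, cs)
  ny <- nrow(sealing$values); nx <- ncol(sealing$values)
  xc <- raster_x_centers(sealing); yc <- raster_y_centers(sealing)

  # rural background: lognormal heterogeneity around the rural mean
  bg <- config$rural_sealing *
    exp(stats::rnorm(nx * ny, sd = config$rural_sealing_sdlog))
  seal <- matrix(pmin(bg, 30), nrow = ny, ncol = nx)

  # radial bump added in place, truncated at 4 radii for speed; pow = 2 is a
  # Gaussian profile, pow = 4 a plateau (super-Gaussian) as in compact city
  # cores whose building height is roughly uniform and falls off sharply
  add_bump <- function(mat, x0, y0, r, amp, pow = 2) {
    cols <- which(abs(xc - x0) <= 4 * r)
    rows <- which(abs(yc - y0) <= 4 * r)
    if (length(cols) == 0 || length(rows) == 0) return(mat)
    d2 <- outer((yc[rows] - y0)^2, (xc[cols] - x0)^2, "+")
    prof <- exp(-0.5 * (d2 / r^2)^(pow / 2))
    mat[rows, cols] <- mat[rows, cols] + amp * prof
    mat
  }

  cores <- place_cores(config, window)
  # administrative boundaries follow settlement: a city-core census tract is
  # drawn around the historical centre, so cores sit at tract centres
  tract_size <- w / (config$n_communities * config$tracts_per_community)
  snap <- function(v) (floor(v / tract_size) + 0.5) * tract_size
  cores$x <- snap(cores$x)
  cores$y <- snap(cores$y)
  hgt <- matrix(0, nrow = ny, ncol = nx)
  for (k in seq_len(nrow(cores))) {
    seal <- add_bump(seal, cores$x[k], cores$y[k], cores$radius[k],
                     config$core_sealing, pow = 4)
    hgt <- add_bump(hgt, cores$x[k], cores$y[k], cores$radius[k], 1, pow = 4)
  }

  # secondary towns: sealed settlement without height bias
  if (config$n_towns > 0) {
    tx <- stats::runif(config$n_towns, window[1] + 500, window[2] - 500)
    ty <- stats::runif(config$n_towns, window[3] + 500, window[4] - 500)
    tr <- stats::runif(config$n_towns, config$town_radius[1], config$town_radius[2])
    for (k in seq_len(config$n_towns)) {
      seal <- add_bump(seal, tx[k], ty[k], tr[k], config$town_sealing)
    }
  }
  sealing$values <- pmin(seal, 100)
  height <- rr_raster(1 + pmin(hgt, 1) * (config$height_max - 1),
                      xmin = 0, ymin = 0, cellsize = cs)

  parts <- make_partitions(config)
  communities <- parts$communities
  tracts <- parts$tracts

  # community counts: proportional to built mass (sealing x height), noised,
  # scaled to the configured total
  built <- sealing$values * height$values
  cid <- partition_cell_ids(sealing, communities)
  mass <- rowsum_by_id(as.vector(built), cid, nrow(communities))
  mass <- mass * exp(stats::rnorm(nrow(communities), sd = config$community_noise_sdlog))
  communities$population <- config$total_population * mass / sum(mass)

  true_pop <- make_true_population(communities, sealing, height)
  biased <- disaggregate_population(communities, sealing)

  tracts <- summarise_tracts(tracts, true_pop, biased$estimate)

  structure(
    list(window = window, config = config, seed = seed,
         sealing = sealing, height_factor = height,
         true_population = true_pop, biased_estimate = biased$estimate,
         communities = communities, tracts = tracts, cores = cores),
    class = "rr_region"
  )
}

place_cores <- function(config, window) {
  n <- config$n_cores
  if (n == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), radius = numeric()))
  }
  margin <- 3 * config$core_radius + 500
  min_sep <- max(4 * config$core_radius, (window[2] - window[1]) / (n + 1))
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < n && tries < 500) {
    tries <- tries + 1
    cx <- stats::runif(1, window[1] + margin, window[2] - margin)
    cy <- stats::runif(1, window[3] + margin, window[4] - margin)
    if (length(xs) == 0 || all(sqrt((xs - cx)^2 + (ys - cy)^2) >= min_sep)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  while (length(xs) < n) { # give up on separation, keep determinism
    xs <- c(xs, stats::runif(1, window[1] + margin, window[2] - margin))
    ys <- c(ys, stats::runif(1, window[3] + margin, window[4] - margin))
  }
  tibble::tibble(x = xs, y = ys, radius = config$core_radius)
}

make_partitions <- function(config) {
  w <- config$window_size
  ncx <- config$n_communities
  ntx <- config$tracts_per_community
  cw <- w / ncx
  tw <- cw / ntx
  grid_rects <- function(nside, size) {
    ij <- expand.grid(ix = seq_len(nside), iy = seq_len(nside))
    tibble::tibble(
      xmin = (ij$ix - 1) * size, xmax = ij$ix * size,
      ymin = (ij$iy - 1) * size, ymax = ij$iy * size
    )
  }
  communities <- grid_rects(ncx, cw)
  communities$community_id <- seq_len(nrow(communities))
  nt <- ncx * ntx
  tracts <- grid_rects(nt, tw)
  tracts$tract_id <- seq_len(nrow(tracts))
  tracts$community_id <- vapply(seq_len(nrow(tracts)), function(i) {
    cxi <- min(floor((tracts$xmin[i] + tw / 2) / cw) + 1, ncx)
    cyi <- min(floor((tracts$ymin[i] + tw / 2) / cw) + 1, ncx)
    which(communities$xmin == (cxi - 1) * cw & communities$ymin == (cyi - 1) * cw)
  }, integer(1))
  list(
    communities = communities[, c("community_id", "xmin", "xmax", "ymin", "ymax")],
    tracts = tracts[, c("tract_id", "community_id", "xmin", "xmax", "ymin", "ymax")]
  )
}

# integer id of the containing rectangle for every raster cell (0 = none)
partition_cell_ids <- function(r, rects) {
  xc <- raster_x_centers(r); yc <- raster_y_centers(r)
  ny <- nrow(r$values); nx <- ncol(r$values)
  id <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(rects))) {
    cols <- which(xc >= rects$xmin[i] & xc < rects$xmax[i])
    rows <- which(yc >= rects$ymin[i] & yc < rects$ymax[i])
    id[rows, cols] <- i
  }
  as.vector(id)
}

rowsum_by_id <- function(v, id, n) {
  out <- numeric(n)
  s <- rowsum(v, id)
  keep <- as.integer(rownames(s))
  pos <- keep > 0
  out[keep[pos]] <- s[pos, 1]
  out
}

#' Dasymetric disaggregation of community counts by surface sealing
#'
#' Spreads each community's population over the cells of the sealing raster
#' proportionally to the sealing value. This is the (deliberately) biased
#' estimate: it ignores building height, so dense high-rise cores receive too
#' little population and rural cells too much. Mass is preserved exactly per
#' community.
#'
#' @param communities Tibble with columns `community_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`, `population`.
#' @param sealing [rr_raster] of sealing in percent, covering all communities.
#' @param weight_extra Optional raster of extra multiplicative weights on the
#'   same grid (used internally for the true population).
#' @return A list of class `rr_biased_grid` with elements `estimate` (an
#'   [rr_raster] of persons per cell) and `cellsize`.
#' @export
disaggregate_population <- function(communities, sealing, weight_extra = NULL) {
  stopifnot(inherits(sealing, "rr_raster"))
  if (any(communities$population < 0)) {
    stop("negative community population counts", call. = FALSE)
  }
  if (!is.null(weight_extra)) stopifnot_same_grid(sealing, weight_extra)
  wmat <- sealing$values
  if (!is.null(weight_extra)) wmat <- wmat * weight_extra$values
  if (any(wmat < 0)) stop("negative weights", call. = FALSE)
  id <- partition_cell_ids(sealing, communities)
  wv <- as.vector(wmat)
  totals <- rowsum_by_id(wv, id, nrow(communities))
  bad <- which(totals <= 0 & communities$population > 0)
  if (length(bad) > 0) {
    stop(sprintf("community %s has positive population but zero sealed area",
                 paste(communities$community_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  share <- numeric(length(wv))
  inside <- id > 0 & totals[pmax(id, 1L)] > 0
  share[inside] <- communities$population[id[inside]] * wv[inside] / totals[id[inside]]
  out <- rr_raster(matrix(share, nrow = nrow(wmat), ncol = ncol(wmat)),
                   xmin = sealing$xmin, ymin = sealing$ymin,
                   cellsize = sealing$cellsize)
  structure(list(estimate = out, cellsize = sealing$cellsize),
            class = "rr_biased_grid")
}

#' True population surface (sealing x building height)
#'
#' Same mass-preserving disaggregation as [disaggregate_population()], but
#' with cell weights proportional to sealing times the building-height
#' multiplier — the ground truth the biased estimate fails to see. With a
#' height factor identically 1 the result equals the biased estimate exactly.
#'
#' @inheritParams disaggregate_population
#' @param height_factor [rr_raster] >= 1 on the sealing grid.
#' @return An [rr_raster] of persons per cell.
#' @export
make_true_population <- function(communities, sealing, height_factor) {
  stopifnot(inherits(height_factor, "rr_raster"))
  if (any(height_factor$values < 1)) {
    stop("height_factor must be >= 1 everywhere", call. = FALSE)
  }
  disaggregate_population(communities, sealing, weight_extra = height_factor)$estimate
}

#' Relative error of estimated versus true counts
#'
#' `100 * (estimated - true) / true`, in percent. Tracts with a true count of
#' zero have undefined error and are returned as `NA` (with a warning) so they
#' can be excluded from threshold analyses.
#'
#' @param estimated,true Numeric vectors of estimated and true counts.
#' @return Numeric vector of relative errors in percent.
#' @export
relative_error <- function(estimated, true) {
  if (any(true < 0, na.rm = TRUE)) stop("negative true counts", call. = FALSE)
  out <- ifelse(true > 0, (estimated - true) / true * 100, NA_real_)
  if (any(true == 0, na.rm = TRUE)) {
    warning(sprintf("%d tract(s) with zero true count: relative error undefined, returned NA",
                    sum(true == 0, na.rm = TRUE)), call. = FALSE)
  }
  out
}

summarise_tracts <- function(tracts, true_pop, estimate) {
  id <- partition_cell_ids(true_pop, tracts)
  y_true <- rowsum_by_id(as.vector(true_pop$values), id, nrow(tracts))
  y_hat <- rowsum_by_id(as.vector(estimate$values), id, nrow(tracts))
  tracts$y_true <- y_true
  tracts$y_hat <- y_hat
  tracts$re_percent <- suppressWarnings(relative_error(y_hat, y_true))
  tracts
}

#' Derive the true risk areas from tract relative errors
#'
#' Tracts whose relative error falls below the threshold are selected and
#' buffered; the buffered union is rasterized onto the analysis grid (cell
#' centre within `buffer_m` of a selected tract) as the boolean truth mask for
#' overlay scoring. Thresholding is available in two modes: a fixed percent
#' cutoff (default -50) or a quantile of the ascending relative-error
#' distribution (default 0.75), since a fixed cutoff and a quartile need not
#' coincide on generated data. Tracts with undefined error (`NA`) are
#' excluded.
#'
#' @param tracts Tibble with `tract_id`, rectangle bounds and `re_percent`.
#' @param analysis_grid [rr_raster] template defining the analysis grid.
#' @param threshold Percent cutoff (mode `"percent"`) or probability (mode
#'   `"quantile"`).
#' @param mode `"percent"` or `"quantile"`.
#' @param buffer_m Buffer radius (metres) applied to selected tracts.
#' @return An object of class `rr_risk_mask`: list with `mask` (logical-valued
#'   [rr_raster]), `selected` (tibble of selected tracts), `threshold_percent`
#'   (the cutoff actually applied), `mode` and `buffer_m`.
#' @export
derive_risk_areas <- function(tracts, analysis_grid,
                              threshold = -50,
                              mode = c("percent", "quantile"),
                              buffer_m = 500) {
  mode <- match.arg(mode)
  re <- tracts$re_percent
  cutoff <- if (mode == "percent") {
    threshold
  } else {
    stopifnot(threshold > 0, threshold < 1)
    unname(stats::quantile(re, probs = threshold, na.rm = TRUE, type = 7))
  }
  sel <- !is.na(re) & re < cutoff
  selected <- tracts[sel, , drop = FALSE]
  mask <- raster_template(raster_window(analysis_grid), analysis_grid$cellsize)
  if (nrow(selected) == 0) {
    warning("no tract below the relative-error threshold: empty risk mask",
            call. = FALSE)
  } else {
    xc <- raster_x_centers(mask); yc <- raster_y_centers(mask)
    m <- matrix(FALSE, nrow = nrow(mask$values), ncol = ncol(mask$values))
    for (i in seq_len(nrow(selected))) {
      dx <- pmax(selected$xmin[i] - xc, xc - selected$xmax[i], 0)
      dy <- pmax(selected$ymin[i] - yc, yc - selected$ymax[i], 0)
      m <- m | outer(dy^2, dx^2, "+") <= buffer_m^2
    }
    mask$values <- m * 1
  }
  structure(
    list(mask = mask, selected = selected, threshold_percent = cutoff,
         mode = mode, buffer_m = buffer_m),
    class = "rr_risk_mask"
  )
}

#' Sample a point pattern proportional to a weight raster
#'
#' Cells are drawn (with replacement) with probability proportional to their
#' weight; each point is then placed uniformly within its cell. Cases are
#' sampled from the true population surface (constant individual risk makes
#' the case density mirror the truth); controls from the biased dasymetric
#' estimate.
#'
#' @param weight [rr_raster] of non-negative weights with positive total.
#' @param n Number of points (>= 1).
#' @param seed Optional integer seed.
#' @param label Optional label (`"case"`/`"control"`).
#' @return An `rr_points` pattern on the raster's window.
#' @export
sample_point_pattern <- function(weight, n, seed = NULL, label = NULL) {
  stopifnot(inherits(weight, "rr_raster"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  wv <- as.vector(weight$values)
  if (any(wv < 0)) stop("negative weights", call. = FALSE)
  if (sum(wv) <= 0) stop("all-zero weight raster", call. = FALSE)
  ny <- nrow(weight$values)
  idx <- sample.int(length(wv), size = n, replace = TRUE, prob = wv)
  col <- (idx - 1L) %/% ny + 1L
  row <- (idx - 1L) %% ny + 1L
  cs <- weight$cellsize
  x <- weight$xmin + (col - 1L) * cs + stats::runif(n) * cs
  y <- raster_ymax(weight) - (row - 1L) * cs - stats::runif(n) * cs
  point_pattern(x, y, window = raster_window(weight), label = label)
}

#' @export
print.rr_region <- function(x, ...) {
  cat(sprintf(
    "<rr_region> %g x %g m window; %d communities, %d tracts, %d urban cores; %.0f persons\n",
    x$window[2] - x$window[1], x$window[4] - x$window[3],
    nrow(x$communities), nrow(x$tracts), nrow(x$cores),
    sum(x$communities$population)
  ))
  invisible(x)
}

#' @export
tidy.rr_region <- function(x, ...) tibble::as_tibble(x$tracts)

#' @export
glance.rr_region <- function(x, ...) {
  tibble::tibble(
    n_communities = nrow(x$communities),
    n_tracts = nrow(x$tracts),
    n_cores = nrow(x$cores),
    total_population = sum(x$communities$population),
    median_re = stats::median(x$tracts$re_percent, na.rm = TRUE)
  )
}

#' @export
autoplot.rr_region <- function(object, ...) {
  autoplot.rr_raster(object$sealing) +
    ggplot2::geom_point(
      data = object$cores,
      ggplot2::aes(x = .data$x, y = .data$y), inherit.aes = FALSE,
      shape = 3, colour = "red"
    ) +
    ggplot2::labs(fill = "sealing [%]", title = "Synthetic study region")
}

#' Write tract polygons as GeoJSON
#'
#' Each tract becomes a rectangular Polygon feature with properties `id`,
#' `y_true`, `y_hat` and `re_percent`.
#'
#' @param tracts Tract tibble (from an `rr_region`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracts_geojson <- function(tracts, path) {
  feats <- purrr::pmap(tracts, function(tract_id, xmin, xmax, ymin, ymax,
                                        y_true = NA, y_hat = NA,
                                        re_percent = NA, ...) {
    ring <- list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                 c(xmin, ymax), c(xmin, ymin))
    list(
      type = "Feature",
      properties = list(id = tract_id, y_true = y_true, y_hat = y_hat,
                        re_percent = re_percent),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
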