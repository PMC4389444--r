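# shared fixtures, all generated in code

# a small raster whose values are all zero, cell size 1 m
toy_grid <- function(n = 10, cellsize = 1, xmin = 0, ymin = 0) {
  raster_template(c(xmin, xmin + n * cellsize, ymin, ymin + n * cellsize), cellsize)
}

# single community covering a 1-row sealing raster with given cell values
toy_community_raster <- function(sealing_values, population, cellsize = 1) {
  ncell <- length(sealing_values)
  sealing <- rr_raster(matrix(sealing_values, nrow = 1), cellsize = cellsize)
  communities <- tibble::tibble(
    community_id = 1L, xmin = 0, xmax = ncell * cellsize,
    ymin = 0, ymax = cellsize, population = population
  )
  list(communities = communities, sealing = sealing)
}

# fast, small study region: 4.8 km window, one urban core
mini_region_config <- function(...) {
  region_config(
    window_size = 4800, pop_cellsize = 40, analysis_cellsize = 200,
    n_communities = 3, tracts_per_community = 2,
    n_cores = 1, core_radius = 400, n_towns = 6,
    total_population = 2e4, ...
  )
}

mini_study_config <- function(...) {
  study_config(region = mini_region_config(), n_cases = 150, ...)
}

# independent brute-force bivariate-Gaussian KDE with Diggle correction,
# used as the oracle for the vectorised implementation
brute_kde_at <- function(xq, yq, px, py, h, window, edge = TRUE) {
  n <- length(px)
  h <- rep_len(h, n)
  val <- 0
  for (i in seq_len(n)) {
    k <- (1 / (2 * pi * h[i]^2)) *
      exp(-((xq - px[i])^2 + (yq - py[i])^2) / (2 * h[i]^2))
    if (edge) {
      e <- (pnorm((window[2] - px[i]) / h[i]) - pnorm((window[1] - px[i]) / h[i])) *
        (pnorm((window[4] - py[i]) / h[i]) - pnorm((window[3] - py[i]) / h[i]))
      k <- k / e
    }
    val <- val + k
  }
  val / n
}

# independent implementation of the LSCV criterion (naive double loop over
# the full distance matrix)
brute_lscv_score <- function(h, x, y) {
  n <- length(x)
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  vapply(h, function(hh) {
    conv <- sum(exp(-d2 / (4 * hh^2))) / (4 * pi * hh^2) # includes diagonal
    loo <- sum(exp(-d2[row(d2) != col(d2)] / (2 * hh^2))) / (2 * pi * hh^2)
    conv / n^2 - 2 * loo / (n * (n - 1))
  }, numeric(1))
}
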