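test_that("a single kernel evaluates to the Gaussian peak at its centre", {
  grid <- toy_grid(11) # centres at 0.5 .. 10.5
  pat <- tibble::tibble(x = 5.5, y = 5.5)
  h <- 0.5
  f <- fixed_kde(pat, h, grid, edge_correction = "none")
  expect_equal(raster_value_at(f$raster, 5.5, 5.5), 1 / (2 * pi * h^2))
})

test_that("two-point pattern matches the closed form at the midpoint", {
  grid <- toy_grid(11)
  pat <- tibble::tibble(x = c(4.5, 6.5), y = c(5.5, 5.5))
  h <- 1.2
  f <- fixed_kde(pat, h, grid, edge_correction = "none")
  # each point is 1 m from the midpoint
  expected <- 2 * (1 / 2) * (1 / (2 * pi * h^2)) * exp(-1 / (2 * h^2))
  expect_equal(raster_value_at(f$raster, 5.5, 5.5), expected, tolerance = 1e-12)
})

test_that("gridded KDE agrees with the brute-force oracle to 1e-12", {
  grid <- toy_grid(6)
  window <- raster_window(grid)
  pat <- tibble::tibble(x = c(1.2, 3.7, 5.1), y = c(0.8, 4.4, 2.9))
  hs <- c(1, 2, 4)
  f <- adaptive_kde(pat, hs, grid, edge_correction = "diggle")
  for (i in 1:6) for (j in 1:6) {
    xq <- raster_x_centers(grid)[j]; yq <- raster_y_centers(grid)[i]
    expect_equal(f$raster$values[i, j],
                 brute_kde_at(xq, yq, pat$x, pat$y, hs, window, edge = TRUE),
                 tolerance = 1e-12)
  }
  # fixed path against the same oracle, without correction
  ff <- fixed_kde(pat, 1.5, grid, edge_correction = "none")
  expect_equal(raster_value_at(ff$raster, 2.5, 2.5),
               brute_kde_at(2.5, 2.5, pat$x, pat$y, 1.5, window, edge = FALSE),
               tolerance = 1e-12)
})

test_that("adaptive KDE with constant bandwidths equals the fixed KDE", {
  set.seed(20)
  grid <- toy_grid(8)
  pat <- tibble::tibble(x = runif(30, 0, 8), y = runif(30, 0, 8))
  f1 <- fixed_kde(pat, 1.1, grid)
  f2 <- adaptive_kde(pat, rep(1.1, 30), grid)
  expect_identical(f1$raster$values, f2$raster$values)
  expect_error(adaptive_kde(pat, rep(1, 29), grid), "length mismatch")
})

test_that("peak height scales with the inverse squared bandwidth", {
  grid <- toy_grid(21)
  pat <- tibble::tibble(x = 10.5, y = 10.5)
  small <- fixed_kde(pat, 0.4, grid, edge_correction = "none")
  large <- fixed_kde(pat, 1.6, grid, edge_correction = "none")
  expect_equal(max(small$raster$values) / max(large$raster$values),
               (1.6 / 0.4)^2, tolerance = 1e-9)
})

test_that("edge factors give the half- and quarter-plane masses", {
  w <- c(0, 100, 0, 100)
  expect_equal(edge_correct_factor(50, 50, 1, w), 1, tolerance = 1e-9)
  expect_equal(edge_correct_factor(0, 50, 1, w), 0.5, tolerance = 1e-9)
  expect_equal(edge_correct_factor(0, 0, 1, w), 0.25, tolerance = 1e-9)
  expect_equal(edge_correct_factor(100, 100, 1, w), 0.25, tolerance = 1e-9)
})

test_that("edge-corrected density integrates to one near a corner", {
  grid <- raster_template(c(0, 20, 0, 20), 0.25)
  pat <- tibble::tibble(x = c(1, 0.3, 10), y = c(1, 0.5, 10))
  f <- fixed_kde(pat, 1, grid, edge_correction = "diggle")
  expect_equal(density_integral(f), 1, tolerance = 0.02)
  # uncorrected estimate loses the corner mass
  f0 <- fixed_kde(pat, 1, grid, edge_correction = "none")
  expect_lt(density_integral(f0), 0.95)
})

test_that("Abramson bandwidths invert the pilot density and keep their geometric mean", {
  pat <- tibble::tibble(x = c(0, 1), y = c(0, 0))
  # pilot densities 1 and 4 per unit area, h0 = 1 -> h = (sqrt(2), 1/sqrt(2))
  h <- adaptive_bandwidths(pat, c(1, 4), h0 = 1)
  expect_equal(h, c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
  # uniform pilot: all bandwidths equal h0
  h2 <- adaptive_bandwidths(pat, c(3, 3), h0 = 2.5)
  expect_equal(h2, c(2.5, 2.5))
  # geometric-mean normalisation on random patterns
  set.seed(30)
  for (k in 1:10) {
    n <- sample(20:200, 1)
    p <- tibble::tibble(x = runif(n), y = runif(n))
    f <- pmax(rexp(n), 1e-6)
    h0 <- runif(1, 0.1, 10)
    hi <- adaptive_bandwidths(p, f, h0)
    expect_equal(exp(mean(log(hi))), h0, tolerance = 1e-9)
  }
})

test_that("denser clusters receive smaller adaptive bandwidths", {
  set.seed(31)
  dense <- tibble::tibble(x = rnorm(200, 0, 0.5), y = rnorm(200, 0, 0.5))
  sparse <- tibble::tibble(x = rnorm(20, 10, 0.5), y = rnorm(20, 10, 0.5))
  pat <- dplyr::bind_rows(dense, sparse)
  attr(pat, "window") <- c(-5, 15, -5, 15)
  pilot <- kde_at_points(pat, 1, pat)
  hi <- adaptive_bandwidths(pat, pilot, h0 = 1)
  expect_lt(mean(hi[1:200]), mean(hi[201:220]))
})

test_that("the oversmoothed estimate loses accuracy against the truth", {
  # integrated squared error of the OS-bandwidth KDE is below that of a
  # deliberately 4x-oversmoothed estimate, for a known bivariate normal
  set.seed(32)
  n <- 1e4
  pat <- tibble::tibble(x = rnorm(n), y = rnorm(n))
  grid <- raster_template(c(-5, 5, -5, 5), 0.2)
  h_os <- os_bandwidth(pat)
  ise <- function(h) {
    f <- fixed_kde(pat, h, grid, edge_correction = "diggle")
    truth <- outer(dnorm(raster_y_centers(grid)), dnorm(raster_x_centers(grid)))
    sum((f$raster$values - truth)^2) * raster_cell_area(grid)
  }
  expect_lt(ise(h_os), ise(4 * h_os))
})
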