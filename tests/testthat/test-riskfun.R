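make_density <- function(values_raster, pattern, h, grid) {
  fixed_kde(pattern, h, grid)
}

test_that("log relative risk is the cellwise log ratio", {
  grid <- toy_grid(4)
  f <- grid; f$values[] <- 1e-8
  g <- grid; g$values[] <- 1e-8
  expect_true(all(log_relative_risk(f, g)$values == 0))
  f2 <- grid; f2$values[] <- 2e-8
  expect_equal(log_relative_risk(f2, g)$values,
               matrix(log(2), 4, 4), tolerance = 1e-12)
  f3 <- grid; f3$values[1, 1] <- 3e-8
  g3 <- grid; g3$values[1, 1] <- 1e-8
  expect_equal(log_relative_risk(f3, g3)$values[1, 1], log(3), tolerance = 1e-12)
  # grid mismatch is an error
  expect_error(log_relative_risk(f, toy_grid(5)), "same grid")
})

test_that("swapping cases and controls negates log risk and z", {
  set.seed(40)
  grid <- toy_grid(10)
  ca <- tibble::tibble(x = runif(80, 0, 10), y = runif(80, 0, 10))
  co <- tibble::tibble(x = runif(60, 0, 10), y = runif(60, 0, 10))
  f <- fixed_kde(ca, 1.5, grid)
  g <- fixed_kde(co, 1.5, grid)
  r1 <- log_relative_risk(f, g)
  r2 <- log_relative_risk(g, f)
  expect_equal(r1$values, -r2$values, tolerance = 1e-12)
  z1 <- asymptotic_z(r1, f, g)
  z2 <- asymptotic_z(r2, g, f)
  expect_equal(z1$values, -z2$values, tolerance = 1e-12)
})

test_that("z is zero at null cells and scales as sqrt(n)", {
  set.seed(41)
  grid <- toy_grid(10)
  pat <- tibble::tibble(x = runif(50, 0, 10), y = runif(50, 0, 10))
  f <- fixed_kde(pat, 2, grid)
  lrr <- log_relative_risk(f, f)
  z <- asymptotic_z(lrr, f, f)
  expect_true(all(z$values == 0))
  # doubling both sample sizes at identical surfaces scales z by sqrt(2)
  ca <- tibble::tibble(x = runif(50, 0, 10), y = runif(50, 0, 10))
  g <- fixed_kde(ca, 2, grid)
  lrr2 <- log_relative_risk(f, g)
  z_a <- asymptotic_z(lrr2, f, g, n_f = 50, n_g = 50)
  z_b <- asymptotic_z(lrr2, f, g, n_f = 100, n_g = 100)
  expect_equal(z_b$values, sqrt(2) * z_a$values, tolerance = 1e-12)
})

test_that("a radial z bump yields a circular tolerance contour of the right area", {
  grid <- raster_template(c(0, 100, 0, 100), 0.5)
  xc <- raster_x_centers(grid); yc <- raster_y_centers(grid)
  R <- 15
  zval <- 3 * exp(-outer((yc - 50)^2, (xc - 50)^2, "+") / (2 * R^2))
  z <- rr_raster(zval, 0, 0, 0.5)
  tc <- tolerance_contours(p_surface(z), alpha = 0.05)
  # z = qnorm(0.95) at radius r*; both the mask and the traced ring must
  # recover the analytic disc
  rstar <- R * sqrt(2 * log(3 / qnorm(0.95)))
  disc <- pi * rstar^2
  expect_equal(nrow(contour_ring_areas(tc)), 1)
  expect_lt(abs(contour_ring_areas(tc)$area_m2 - disc) / disc, 0.05)
  expect_lt(abs(tc$significant_area_m2 - disc) / disc, 0.05)
})

test_that("degenerate p surfaces give empty or full significant sets", {
  grid <- toy_grid(5)
  p1 <- grid; p1$values[] <- 1
  tc <- tolerance_contours(p1, 0.05)
  expect_equal(sum(tc$mask$values), 0)
  expect_equal(nrow(tc$polygons), 0)
  tc_all <- tolerance_contours(p1, 1)
  expect_equal(sum(tc_all$mask$values), 25)
})

test_that("the significant mask is exactly the rasterized p < alpha set", {
  set.seed(42)
  grid <- toy_grid(8)
  p <- grid; p$values[] <- runif(64)
  p$values[2, 3] <- NA
  tc <- tolerance_contours(p, 0.3)
  expect_equal(tc$mask$values > 0, !is.na(p$values) & p$values < 0.3)
})

test_that("risk_surface ties the pieces together for both estimators", {
  set.seed(43)
  reg <- simulate_region(mini_region_config(), seed = 43)
  grid <- raster_template(reg$window, 300)
  ca <- sample_point_pattern(reg$true_population, 120)
  co <- sample_point_pattern(reg$biased_estimate, 120)
  spec <- bandwidth_spec(h_fixed = 500, h0_global = 561,
                         h_pilot_f = 150, h_pilot_g = 150)
  for (est in c("fixed", "adaptive")) {
    rs <- risk_surface(ca, co, spec, grid, estimator = est)
    expect_s3_class(rs, "rr_risk_surface")
    expect_true(all(is.finite(rs$z$values) | is.na(rs$z$values)))
    pv <- rs$p$values
    expect_true(all(pv[!is.na(pv)] > 0 & pv[!is.na(pv)] <= 1))
    # densities normalise over the window
    expect_equal(density_integral(rs$f), 1, tolerance = 0.02)
    expect_equal(density_integral(rs$g), 1, tolerance = 0.02)
    g <- glance(rs)
    expect_equal(g$estimator, est)
    td <- tidy(rs)
    expect_equal(nrow(td), prod(dim(grid)))
  }
  # adaptive surfaces honour the geometric-mean constraint
  rs_a <- risk_surface(ca, co, spec, grid, estimator = "adaptive")
  expect_equal(exp(mean(log(rs_a$f$per_point_h))), spec$h0_global,
               tolerance = 1e-6)
  # contour export is valid GeoJSON
  path <- withr::local_tempfile(fileext = ".geojson")
  write_contours_geojson(rs_a, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
})
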