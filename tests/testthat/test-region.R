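test_that("disaggregation splits community counts proportionally to sealing", {
  f <- toy_community_raster(c(75, 25), population = 100)
  out <- disaggregate_population(f$communities, f$sealing)
  expect_equal(as.vector(out$estimate$values), c(75, 25))

  f0 <- toy_community_raster(c(75, 25), population = 0)
  expect_equal(as.vector(disaggregate_population(f0$communities, f0$sealing)$estimate$values),
               c(0, 0))

  f3 <- toy_community_raster(c(10, 10, 80), population = 50)
  expect_equal(as.vector(disaggregate_population(f3$communities, f3$sealing)$estimate$values),
               c(5, 5, 40))
})

test_that("disaggregation errors name the offending community", {
  f <- toy_community_raster(c(0, 0), population = 10)
  expect_error(disaggregate_population(f$communities, f$sealing), "community 1")
  f$communities$population <- -5
  expect_error(disaggregate_population(f$communities, f$sealing), "negative")
})

test_that("true population reduces to the biased estimate when height is 1", {
  f <- toy_community_raster(c(30, 10, 60), population = 200)
  h1 <- rr_raster(matrix(1, nrow = 1, ncol = 3), cellsize = 1)
  expect_equal(make_true_population(f$communities, f$sealing, h1)$values,
               disaggregate_population(f$communities, f$sealing)$estimate$values)
})

test_that("height multiplier shifts mass urban-wards and renormalises per community", {
  f <- toy_community_raster(c(50, 50), population = 100)
  h <- rr_raster(matrix(c(4, 1), nrow = 1), cellsize = 1)
  out <- make_true_population(f$communities, f$sealing, h)
  expect_equal(as.vector(out$values), c(80, 20)) # 4/5 of the count in the tall cell
  # uniform doubling of height within the community changes nothing
  h2 <- rr_raster(matrix(c(8, 2), nrow = 1), cellsize = 1)
  expect_equal(make_true_population(f$communities, f$sealing, h2)$values, out$values)
  expect_error(make_true_population(f$communities, f$sealing,
                                    rr_raster(matrix(c(0.5, 1), nrow = 1), cellsize = 1)),
               ">= 1")
})

test_that("relative error follows the percent formula and flags zero truth", {
  expect_equal(relative_error(50, 100), -50)
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(150, 100), 50)
  expect_warning(re <- relative_error(c(10, 5), c(100, 0)), "zero true")
  expect_equal(re, c(-90, NA))
  expect_error(relative_error(10, -1), "negative")
})

test_that("risk-area selection respects threshold, both modes", {
  tracts <- tibble::tibble(
    tract_id = 1:3, community_id = 1L,
    xmin = c(0, 100, 200), xmax = c(100, 200, 300),
    ymin = 0, ymax = 100,
    re_percent = c(-80, -30, 10)
  )
  grid <- raster_template(c(0, 300, 0, 100), 10)
  rm <- suppressWarnings(derive_risk_areas(tracts, grid, threshold = -50))
  expect_equal(rm$selected$tract_id, 1L)
  # quantile mode: cutoff at the 2/3 quantile of (-80, -30, 10)
  rmq <- derive_risk_areas(tracts, grid, threshold = 2 / 3, mode = "quantile",
                           buffer_m = 0)
  expect_equal(rmq$threshold_percent,
               unname(quantile(tracts$re_percent, 2 / 3)))
  expect_true(all(rmq$selected$re_percent < rmq$threshold_percent))
})

test_that("zero buffer rasterizes exactly the selected tracts", {
  tracts <- tibble::tibble(tract_id = 1L, community_id = 1L,
                           xmin = 100, xmax = 200, ymin = 100, ymax = 200,
                           re_percent = -90)
  grid <- raster_template(c(0, 300, 0, 300), 10)
  rm <- derive_risk_areas(tracts, grid, threshold = -50, buffer_m = 0)
  expect_equal(sum(rm$mask$values) * raster_cell_area(rm$mask), 100 * 100)
})

test_that("buffered mask area matches the Minkowski sum of a square", {
  # 1 km x 1 km tract buffered by 500 m:
  # area = 1e6 + 4 * (1000 * 500) + pi * 500^2
  tracts <- tibble::tibble(tract_id = 1L, community_id = 1L,
                           xmin = 1000, xmax = 2000, ymin = 1000, ymax = 2000,
                           re_percent = -90)
  grid <- raster_template(c(0, 3000, 0, 3000), 5)
  rm <- derive_risk_areas(tracts, grid, threshold = -50, buffer_m = 500)
  expected <- 1e6 + 4 * (1000 * 500) + pi * 500^2
  got <- sum(rm$mask$values) * raster_cell_area(rm$mask)
  expect_lt(abs(got - expected) / expected, 0.01)
})

test_that("no tract below threshold yields an empty mask with a warning", {
  tracts <- tibble::tibble(tract_id = 1L, community_id = 1L,
                           xmin = 0, xmax = 100, ymin = 0, ymax = 100,
                           re_percent = 5)
  grid <- raster_template(c(0, 100, 0, 100), 10)
  expect_warning(rm <- derive_risk_areas(tracts, grid, threshold = -50), "empty")
  expect_equal(sum(rm$mask$values), 0)
})

test_that("point sampling is proportional, in-cell uniform and seed-reproducible", {
  # all mass in one cell
  w <- toy_grid(3)
  w$values[2, 2] <- 1
  pp <- sample_point_pattern(w, 10, seed = 7)
  expect_true(all(pp$x >= 1 & pp$x <= 2 & pp$y >= 1 & pp$y <= 2))

  expect_error(sample_point_pattern(toy_grid(3), 5), "all-zero")

  # same seed identical, different seed different
  w$values[] <- 1
  a <- sample_point_pattern(w, 50, seed = 11)
  b <- sample_point_pattern(w, 50, seed = 11)
  d <- sample_point_pattern(w, 50, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$x, d$x)))

  # quadrant counts of a uniform sample are multinomial(1/4)
  w2 <- toy_grid(2)
  w2$values[] <- 1
  pp2 <- sample_point_pattern(w2, 1e4, seed = 3)
  idx <- raster_cell_index(w2, pp2$x, pp2$y)
  counts <- tabulate(idx$cell, nbins = 4)
  expect_gt(chisq.test(counts, p = rep(1 / 4, 4))$p.value, 0.001)
})

test_that("empirical sampling frequencies converge to normalized weights", {
  set.seed(99)
  w <- toy_grid(5)
  w$values[] <- runif(25, 0.2, 2)
  pp <- sample_point_pattern(w, 1e5, seed = 21)
  idx <- raster_cell_index(w, pp$x, pp$y)
  emp <- tabulate(idx$cell, nbins = 25) / 1e5
  p <- as.vector(w$values) / sum(w$values)
  expect_lt(sum(abs(emp - p)) / 2, 0.01) # total-variation distance
})

test_that("generated regions conserve mass and bias urban tracts downward", {
  for (s in c(2, 13)) {
    reg <- simulate_region(mini_region_config(), seed = s)
    # mass conservation at every level
    expect_equal(sum(reg$true_population$values), sum(reg$communities$population),
                 tolerance = 1e-8)
    expect_equal(sum(reg$biased_estimate$values), sum(reg$communities$population),
                 tolerance = 1e-8)
    tr <- reg$tracts
    by_comm <- tapply(tr$y_true, tr$community_id, sum)
    expect_equal(as.numeric(by_comm[as.character(reg$communities$community_id)]),
                 reg$communities$population, tolerance = 1e-8)
    # bias direction: tracts overlapping a core are underestimated, the rural
    # tracts of the same community overestimated
    core <- reg$cores
    overlaps_core <- tr$xmin <= core$x + core$radius & tr$xmax >= core$x - core$radius &
      tr$ymin <= core$y + core$radius & tr$ymax >= core$y - core$radius
    core_comms <- unique(tr$community_id[overlaps_core])
    expect_lt(max(tr$re_percent[overlaps_core & tr$re_percent < 0], na.rm = TRUE), 0)
    expect_true(min(tr$re_percent[overlaps_core], na.rm = TRUE) < -25)
    rural_same <- tr$community_id %in% core_comms & !overlaps_core
    expect_gt(median(tr$re_percent[rural_same], na.rm = TRUE), 0)
  }
})

test_that("without height bias relative errors vanish and no risk areas emerge", {
  reg <- simulate_region(mini_region_config(height_max = 1), seed = 4)
  expect_lt(max(abs(reg$tracts$re_percent), na.rm = TRUE), 1e-6)
  grid <- raster_template(reg$window, 200)
  expect_warning(rm <- derive_risk_areas(reg$tracts, grid, threshold = -50), "empty")
  expect_equal(sum(rm$mask$values), 0)
})

test_that("tract GeoJSON export is a valid FeatureCollection", {
  reg <- simulate_region(mini_region_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_tracts_geojson(reg$tracts, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(reg$tracts))
  expect_equal(gj$features[[1]]$geometry$type, "Polygon")
  expect_true(!is.null(gj$features[[1]]$properties$re_percent))
})
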