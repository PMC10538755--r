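test_that("conversion factors degrade habitat multiplicatively", {
  expect_equal(apply_conversion(0.500, 0.75), 0.125)
  expect_equal(apply_conversion(0.500, 0), 0.500)
  expect_equal(apply_conversion(0.500, 1.00), 0)
  # vectorised, stays within [0, habitat]
  h <- seq(0, 1, by = 0.1)
  expect_true(all(apply_conversion(h, 0.25) <= h))
  expect_error(apply_conversion(1.2, 0.5), "\\[0, 1\\]")
  expect_error(apply_conversion(0.5, -0.1), "\\[0, 1\\]")
})

test_that("resistance is the complement of adjusted habitat", {
  expect_equal(resistance_from_habitat(0.125), 0.875)
  expect_equal(resistance_from_habitat(0.375), 0.625)
  expect_equal(resistance_from_habitat(1), 0)
  expect_error(resistance_from_habitat(-0.01), "\\[0, 1\\]")
  # complement identity on arbitrary values
  h <- runif(50)
  expect_equal(resistance_from_habitat(h) + h, rep(1, 50))
})

test_that("carrying capacity reproduces the stepped density scale", {
  # one representative value per printed bin, plus the right-closed edges
  expect_identical(carrying_capacity(0), 0L)
  expect_identical(carrying_capacity(0.05), 1L)
  expect_identical(carrying_capacity(0.15), 1L)
  expect_identical(carrying_capacity(0.25), 3L)
  expect_identical(carrying_capacity(0.35), 6L)
  expect_identical(carrying_capacity(0.45), 9L)
  expect_identical(carrying_capacity(0.55), 12L)
  expect_identical(carrying_capacity(0.65), 15L)
  expect_identical(carrying_capacity(0.75), 18L)
  expect_identical(carrying_capacity(0.85), 21L)
  expect_identical(carrying_capacity(0.95), 24L)
  expect_identical(carrying_capacity(c(0.20, 0.30, 1)), c(1L, 3L, 24L))
  # non-increasing in resistance; K = 0 iff resistance = 1
  h <- seq(0, 1, by = 0.01)
  k <- carrying_capacity(h)
  expect_true(all(diff(k) >= 0))
  expect_identical(k == 0L, resistance_from_habitat(h) == 1)
})

test_that("scenario surfaces have the documented geometry and capacity", {
  nb <- build_scenario_surface("no_barrier", density = "low")
  expect_equal(dim(nb$resistance), c(25, 25))
  expect_true(all(nb$resistance == 0))
  expect_true(all(nb$carrying_capacity == 3))
  expect_equal(sum(nb$carrying_capacity), 1875)

  ba <- build_scenario_surface("barrier", density = "moderate")
  expect_equal(sum(ba$resistance == 1), 25)
  expect_equal(sum(ba$resistance == 0), 600)
  expect_true(all(ba$carrying_capacity[ba$resistance == 0] == 14))
  expect_true(all(ba$carrying_capacity[, 13] == 0))

  cu <- build_scenario_surface("culverts", density = "high", n_culverts = 3)
  expect_equal(sum(cu$resistance == 0.7), 3)
  expect_true(all(cu$resistance[cell_df <- cbind(c(7, 13, 19), 13)] == 0.7))
  expect_true(all(cu$carrying_capacity[cell_df] == 3))
  expect_error(build_scenario_surface("culverts", n_culverts = 26), "culvert")
})

test_that("barrier splits the grid in two; culverts reconnect it", {
  expect_equal(n_components(build_scenario_surface("no_barrier")), 1L)
  expect_equal(n_components(build_scenario_surface("barrier")), 2L)
  expect_equal(n_components(build_scenario_surface("culverts")), 1L)
})

test_that("heterogeneous surfaces compose disturbance layers sequentially", {
  hab <- habitat_grid(matrix(0.5, 25, 25))
  rail_mask <- matrix(0, 25, 25); rail_mask[, 10] <- 1
  rail <- disturbance_layer("rail_interstate", rail_mask)
  surf <- build_heterogeneous_surface(hab, list(rail))
  expect_true(all(surf$resistance[, 10] == 0.875))
  expect_true(all(surf$carrying_capacity[, 10] == 1))  # adjusted 0.125
  expect_true(all(surf$resistance[, -10] == 0.5))

  # no layers: plain complement
  plain <- build_heterogeneous_surface(hab)
  expect_true(all(plain$resistance == 0.5))

  # two stacked 0.25 layers: 0.5 * 0.75 * 0.75 = 0.28125
  row <- disturbance_layer("right_of_way", matrix(1, 25, 25))
  two <- build_heterogeneous_surface(hab, list(row, row))
  expect_equal(unique(as.vector(two$resistance)), 1 - 0.28125)

  # minor roads scale with road length relative to the grid maximum
  len <- matrix(0, 25, 25); len[1, 1] <- 2; len[1, 2] <- 1
  mr <- disturbance_layer("minor_road", len)
  m <- build_heterogeneous_surface(hab, list(mr))
  expect_equal(m$resistance[1, 1], 1 - apply_conversion(0.5, 0.25))
  expect_equal(m$resistance[1, 2], 1 - apply_conversion(0.5, 0.125))

  bad <- disturbance_layer("urban_solar", matrix(1, 5, 5))
  expect_error(build_heterogeneous_surface(hab, list(bad)), "co-registered")
})

test_that("composing conversion factors multiplies the retained fractions", {
  f1 <- 0.3; f2 <- 0.45; h <- 0.8
  stacked <- apply_conversion(apply_conversion(h, f1), f2)
  combined <- apply_conversion(h, 1 - (1 - f1) * (1 - f2))
  expect_equal(stacked, combined)
})

test_that("ASCII rasters round-trip bit-exactly and reject bad input", {
  path <- withr::local_tempfile(fileext = ".asc")
  set.seed(1)
  vals <- matrix(round(runif(625), 6), 25, 25)
  write_raster(habitat_grid(vals), path)
  back <- read_raster(path)
  expect_identical(back$values, vals)
  expect_equal(back$n_rows, 25)

  uniform <- matrix(0.5, 25, 25)
  write_raster(habitat_grid(uniform), path)
  expect_true(all(read_raster(path)$values == 0.5))

  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "0.5 1.2"), path)
  expect_error(read_raster(path), "\\[0, 1\\]")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "0.5 0.5", "0.5"), path)
  expect_error(read_raster(path), "rectangular")
})
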