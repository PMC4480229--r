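# Idealized domains and synthetic current/wind fields.

test_that("two_basin_strait builds two basins joined by exactly one strait", {
  g <- grid_spec(-10, -1, 34, 38, 200, 100, daily_times(3))
  sc <- make_scenario("two_basin_strait", g)
  land <- sc$land_mask
  # barrier columns: land columns between two mostly-ocean basins
  bcols <- which(colSums(land) > max(colSums(land[, 1:10])))
  bcols <- bcols[bcols > 20 & bcols < 180]
  expect_true(length(bcols) >= 2)
  # exactly one contiguous ocean gap in each barrier column
  for (i in bcols) {
    runs <- rle(land[, i])
    expect_equal(sum(!runs$values), 1)
  }
  expect_gte(length(sc$beaches), 6)
  # ocean on both sides of the barrier at gap latitudes (west of the
  # eastern closure)
  gap_rows <- which(!land[, bcols[1]])
  expect_true(all(!land[gap_rows, 5]))
  expect_true(all(!land[gap_rows, 180]))
})

test_that("open_coast puts land on the northern edge only", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("open_coast", g)
  land <- sc$land_mask
  land_rows <- which(rowSums(land) > 0)
  expect_true(all(land_rows > 40))            # only the top band
  expect_true(all(land[land_rows, ]))         # full rows of land
  bd <- beaches_df(sc)
  expect_true(all(bd$exposure_deg == 180))    # all face the ocean to the S
  expect_equal(length(unique(bd$lat_mid)), 1L)
})

test_that("an unresolvable strait and unknown presets error out", {
  g_small <- grid_spec(-10, -1, 34, 38, 20, 7, daily_times(3))
  expect_error(make_scenario("two_basin_strait", g_small), "strait")
  g <- grid_spec(-10, -1, 34, 38, 60, 30, daily_times(3))
  expect_error(make_scenario("nonsense", g), "two_basin_strait")
})

test_that("bathymetry rises exponentially offshore through the seeding band", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("open_coast", g, shelf_cells = 8, depth_max = 600)
  land <- sc$land_mask
  depth <- sc$bathymetry
  expect_true(all(depth[land] <= 0))
  expect_true(all(depth[!land] > 0))
  expect_lte(max(depth), 600)
  # one cell off the coast reads 20 m, shelf_cells off reads 200 m
  coast_row <- max(which(rowSums(land) == 0))    # last full-ocean row
  i <- 30
  expect_equal(depth[coast_row, i], 20, tolerance = 1e-9)
  expect_equal(depth[coast_row - 7L, i], 200, tolerance = 1e-9)
  # monotone offshore along a meridional column
  col <- depth[1:coast_row, i]
  expect_true(all(diff(col) <= 1e-9))
})

test_that("beach segments are unique, west-to-east ordered, with geodesic lengths", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("two_basin_strait", g)
  bd <- beaches_df(sc)
  expect_equal(anyDuplicated(bd$id), 0L)
  expect_true(!is.unsorted(bd$lon_mid))
  for (s in sc$beaches) {
    v <- s$vertices
    L <- sum(geosphere::distGeo(v[-nrow(v), , drop = FALSE],
                                v[-1, , drop = FALSE]))
    expect_lt(abs(L - s$length_m) / L, 0.001)
    expect_gt(s$length_m, 0)
  }
})

test_that("scenario generation is exactly reproducible", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  a <- make_scenario("two_basin_strait", g)
  b <- make_scenario("two_basin_strait", g)
  expect_identical(a$land_mask, b$land_mask)
  expect_identical(a$bathymetry, b$bathymetry)
  expect_identical(beaches_df(a), beaches_df(b))
})

test_that("uniform currents read the requested vector on every ocean cell", {
  g <- grid_spec(-10, -1, 34, 38, 60, 30, daily_times(3))
  sc <- make_scenario("open_coast", g)
  f <- make_current_field(sc, "uniform", u = 0.2, v = 0)
  sea <- !sc$land_mask
  expect_true(all(f$u[, , 1][sea] == 0.2))
  expect_true(all(f$v[, , 1][sea] == 0))
  expect_true(all(f$u[, , 1][!sea] == 0))
})

test_that("gyre speed follows the solid-body profile inside the rim", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("single_gyre_basin", g)
  lon0 <- mean(g$lon); lat0 <- mean(g$lat)
  f <- make_current_field(sc, "gyre", center_lon = lon0, center_lat = lat0,
                          peak = 0.5, radius_km = 30,
                          rotation = "anticyclonic")
  # probe at r = 15 km east of the centre: solid-body speed = 0.5 * 15/30
  lp <- lon0 + 15000 / (111194.926 * cos(lat0 * pi / 180))
  s <- field_sample(f, lp, lat0, g$times[1])
  expect_equal(sqrt(s$u^2 + s$v^2), 0.25, tolerance = 1e-6)
  expect_lt(s$v, 0)   # anticyclonic: southward on the eastern side
  expect_error(make_current_field(sc, "gyre", center_lon = g$lon_min + 0.1,
                                  center_lat = g$lat_max - 0.1, peak = 0.5,
                                  radius_km = 30), "ocean")
  expect_error(make_current_field(sc, "vortex"), "arg")
})

test_that("gyre flow does not leak through the basin boundary", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("single_gyre_basin", g)
  f <- make_current_field(sc, "gyre", peak = 0.5, radius_km = 30)
  land <- sc$land_mask
  ny <- g$ny; nx <- g$nx
  worst <- 0
  for (j in 2:(ny - 1)) for (i in 2:(nx - 1)) {
    if (land[j, i]) next
    if (land[j, i + 1] || land[j, i - 1])
      worst <- max(worst, abs(f$u[j, i, 1]))
    if (land[j + 1, i] || land[j - 1, i])
      worst <- max(worst, abs(f$v[j, i, 1]))
  }
  expect_lt(worst, 0.01 * 0.5)
})

test_that("the strait jet carries eastward transport through the strait", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("two_basin_strait", g)
  f <- make_current_field(sc, "strait_jet", speed = 1)
  st <- sc$params$strait
  icol <- which.min(abs(g$lon - st$lon))
  gap <- which(!sc$land_mask[, icol])
  expect_true(all(f$u[gap, icol, 1] > 0))
  # peak jet speed near the requested value (cell discretization and the
  # aperture widening away from the throat shave a few percent)
  expect_gt(max(f$u[gap, icol, 1]), 0.9)
  expect_error(make_current_field(sc, "strait_jet", speed = 5), "cap")
})

test_that("composite fields are the exact sum of their parts", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(3))
  sc <- make_scenario("two_basin_strait", g)
  f1 <- make_current_field(sc, "strait_jet", speed = 1)
  f2 <- make_current_field(sc, "slope_current", speed = 0.3)
  fc <- make_current_field(sc, "composite", components = list(
    list(kind = "strait_jet", speed = 1),
    list(kind = "slope_current", speed = 0.3)))
  expect_identical(fc$u, f1$u + f2$u)
  expect_identical(fc$v, f1$v + f2$v)
})

test_that("wind episodes switch on and off at the stated times", {
  g <- grid_spec(-10, -1, 34, 38, 20, 10, daily_times(40))
  t0 <- g$times[1]
  w <- make_wind_field(g, data.frame(start = t0, end = t0 + 25 * 86400,
                                     u = 8, v = 0))
  s10 <- field_sample(w, -5, 36, t0 + 10 * 86400)
  s30 <- field_sample(w, -5, 36, t0 + 30 * 86400)
  expect_equal(s10$u, 8)
  expect_equal(s30$u, 0)
  w0 <- make_wind_field(g, NULL)
  expect_true(all(w0$u == 0) && all(w0$v == 0))
  expect_error(make_wind_field(g, rbind(
    data.frame(start = t0, end = t0 + 10 * 86400, u = 5, v = 0),
    data.frame(start = t0 + 5 * 86400, end = t0 + 15 * 86400, u = 3, v = 0))),
    "overlap")
  expect_error(make_wind_field(g, data.frame(start = t0, end = t0 + 86400,
                                             u = 50, v = 0)), "cap")
})
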