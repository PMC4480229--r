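# The drift velocity rule and the trajectory integrator.

make_uniform_env <- function(u = 0, v = 0, wu = 0, wv = 0, n_days = 10,
                             preset = "open_coast") {
  g <- grid_spec(-7, -2, 35, 37.5, 100, 50, daily_times(n_days))
  sc <- make_scenario(preset, g)
  cur <- make_current_field(sc, "uniform", u = u, v = v)
  w <- if (wu == 0 && wv == 0) make_wind_field(g, NULL)
       else make_wind_field(g, data.frame(start = g$times[1],
                                          end = g$times[n_days],
                                          u = wu, v = wv))
  drift_environment(sc, cur, w)
}

test_that("drift velocity adds 10% of the wind to the current", {
  env <- make_uniform_env(wu = 5, wv = 0)
  t <- env$scenario$grid$times[2]
  v1 <- drift_velocity(-5, 36, t, env$currents, env$winds)
  expect_equal(v1$u, 0.5)
  expect_equal(v1$v, 0)
  env2 <- make_uniform_env(u = 0.2, v = 0)
  v2 <- drift_velocity(-5, 36, t, env2$currents, env2$winds)
  expect_equal(v2$u, 0.2)
  expect_equal(v2$v, 0)
  expect_error(drift_velocity(-5, 37.4, t, env$currents, env$winds), "land")
  expect_error(drift_velocity(-5, 36, t + 400 * 86400, env$currents,
                              env$winds), "span")
})

test_that("wind-only drift speed equals windage times wind speed", {
  env <- make_uniform_env(wu = 3.7, wv = -2.1)
  t <- env$scenario$grid$times[2]
  lon <- c(-6, -5, -4.2); lat <- c(35.5, 36, 36.8)
  v <- drift_velocity(lon, lat, t, env$currents, env$winds)
  spd <- sqrt(v$u^2 + v$v^2)
  expect_equal(spd, rep(0.1 * sqrt(3.7^2 + 2.1^2), 3), tolerance = 1e-12)
})

test_that("handed colonies deviate by the signed sail angle", {
  env <- make_uniform_env(wu = 10, wv = 0)
  t <- env$scenario$grid$times[2]
  cfg <- drift_config(handedness_enabled = TRUE, theta_max = 15,
                      theta_taper_wind = 10)
  # oracle: direct rotation of the windage vector by 15 degrees
  vr <- drift_velocity(-5, 36, t, env$currents, env$winds, "right", cfg)
  expect_equal(vr$u, 1.0 * cos(15 * pi / 180), tolerance = 1e-12)
  expect_equal(vr$v, -1.0 * sin(15 * pi / 180), tolerance = 1e-12)
  vl <- drift_velocity(-5, 36, t, env$currents, env$winds, "left", cfg)
  expect_equal(vl$v, 1.0 * sin(15 * pi / 180), tolerance = 1e-12)
  vn <- drift_velocity(-5, 36, t, env$currents, env$winds, "none", cfg)
  expect_equal(vn$v, 0)
})

test_that("the sail angle tapers linearly to zero under intense winds", {
  cfg <- drift_config(handedness_enabled = TRUE, theta_max = 12.5,
                      theta_taper_wind = 10)
  th <- windrift:::theta_eff_deg(c(2, 5, 10, 15, 20, 30), cfg)
  expect_equal(th, c(12.5, 12.5, 12.5, 6.25, 0, 0))
})

test_that("configuration bounds are enforced", {
  expect_error(drift_config(windage = 1.2), "windage")
  expect_error(drift_config(handedness_enabled = TRUE, theta_max = 20),
               "theta_max")
  expect_no_error(drift_config(handedness_enabled = FALSE, theta_max = 20))
  expect_error(drift_config(dt = 0), "dt")
})

test_that("all-zero fields leave every colony in place", {
  env <- make_uniform_env()
  pop <- seed_depth_band(env$scenario, 20, 200, n = 50, rng_seed = 2)
  t0 <- env$scenario$grid$times[1]
  run <- run_simulation(pop, env, drift_config(), t0, t0 + 3 * 86400)
  expect_identical(run$population$lon, pop$lon)
  expect_identical(run$population$lat, pop$lat)
  expect_true(all(run$population$status == "active"))
  expect_equal(nrow(run$strandings), 0L)
})

test_that("uniform flow displaces colonies by exactly u times t", {
  env <- make_uniform_env(u = 0.1, v = 0)
  t0 <- env$scenario$grid$times[1]
  pop <- point_population(c(-6, -5.5), c(35.5, 36))
  run <- run_simulation(pop, env, drift_config(), t0, t0 + 86400)
  disp <- (run$population$lon - pop$lon) * 111194.926 *
    cos(pop$lat * pi / 180)
  expect_equal(disp, c(8640, 8640), tolerance = 1e-6)
  expect_equal(run$population$lat, pop$lat)
})

test_that("onshore flow strands a colony after the predicted transit time", {
  env <- make_uniform_env(v = 0.3)
  g <- env$scenario$grid
  land_rows <- which(rowSums(env$scenario$land_mask) > 0)
  coast_edge <- g$lat_min + (min(land_rows) - 1) * g$dlat
  lat0 <- coast_edge - 0.2
  t0 <- g$times[1]
  run <- run_simulation(point_population(-5, lat0), env,
                        drift_config(dt = 1800), t0, t0 + 5 * 86400)
  expect_equal(run$population$status, "stranded")
  expected <- as.numeric(t0) + 0.2 * 111194.926 / 0.3
  expect_lt(abs(as.numeric(run$strandings$time) - expected), 1800)
  # the recorded crossing sits on the land-ocean boundary
  expect_equal(run$strandings$lat, coast_edge, tolerance = 1e-6)
  expect_false(is.na(run$strandings$segment_id))
})

test_that("colonies leaving the open boundary exit without stranding", {
  env <- make_uniform_env(u = -0.5)
  g <- env$scenario$grid
  t0 <- g$times[1]
  run <- run_simulation(point_population(g$lon_min + 0.05, 36), env,
                        drift_config(), t0, t0 + 2 * 86400)
  expect_equal(run$population$status, "exited")
  expect_equal(nrow(run$strandings), 0L)
  expect_equal(run$population$lon, g$lon_min)
})

test_that("stranded colonies never move again and trajectories terminate", {
  env <- make_uniform_env(v = 0.3)
  g <- env$scenario$grid
  t0 <- g$times[1]
  pop <- point_population(c(-5, -4), c(37.1, 35.2))
  run <- run_simulation(pop, env, drift_config(output_stride = 4L),
                        t0, t0 + 6 * 86400)
  s <- run$strandings
  stranded <- run$population$status == "stranded"
  expect_true(any(stranded))
  expect_equal(run$population$lon[stranded],
               s$lon[match(run$population$id[stranded], s$particle_id)])
  # trajectory is NA after the terminal event
  k <- which(stranded)[1]
  last_seen <- max(which(!is.na(run$trajectories$lat[k, ])))
  expect_lt(last_seen, ncol(run$trajectories$lat))
})

test_that("the particle ledger is conserved at every step", {
  ex <- transport_experiment(n = 300, seed = 5, days = 15)
  cnt <- ex$run$counts
  expect_true(all(cnt$n_active + cnt$n_stranded + cnt$n_exited == 300L))
})

test_that("a backward run retraces a forward run on a steady field", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(10))
  sc <- make_scenario("single_gyre_basin", g)
  gyre <- make_current_field(sc, "gyre", peak = 0.5, radius_km = 30)
  env <- drift_environment(sc, gyre, make_wind_field(g, NULL))
  lon0 <- mean(g$lon) + 15000 / (111194.926 * cos(mean(g$lat) * pi / 180))
  pop <- point_population(lon0, mean(g$lat))
  t0 <- g$times[1]; t1 <- t0 + 2 * 86400
  fw <- run_simulation(pop, env, drift_config(dt = 1800), t0, t1)
  bw <- run_simulation(fw$population, env,
                       drift_config(dt = 1800, direction = "backward"),
                       t1, t0)
  tol <- 1e-3 * g$dlon
  expect_lt(abs(bw$population$lon - pop$lon), tol)
  expect_lt(abs(bw$population$lat - pop$lat), tol)
})

test_that("RK4 keeps a gyre-trapped colony at fixed radius; Euler drifts more", {
  g <- grid_spec(-10, -1, 34, 38, 120, 60, daily_times(33))
  sc <- make_scenario("single_gyre_basin", g)
  gyre <- make_current_field(sc, "gyre", peak = 0.5, radius_km = 30)
  env <- drift_environment(sc, gyre, make_wind_field(g, NULL))
  lat0 <- mean(g$lat)
  lon0 <- mean(g$lon) + 15000 / (111194.926 * cos(lat0 * pi / 180))
  pop <- point_population(lon0, lat0)
  t0 <- g$times[1]
  radius_drift <- function(run) {
    tl <- run$trajectories
    r <- sqrt(((tl$lon - mean(g$lon)) * 111194.926 * cos(lat0 * pi / 180))^2 +
              ((tl$lat - lat0) * 111194.926)^2)
    abs(r[length(r)] - 15000)
  }
  rk4 <- run_simulation(pop, env, drift_config(dt = 1800), t0,
                        t0 + 30 * 86400)
  expect_lt(radius_drift(rk4) / 30000, 0.02)
  eul <- run_simulation(pop, env, drift_config(dt = 1800,
                                               integrator = "euler"),
                        t0, t0 + 30 * 86400)
  expect_gt(radius_drift(eul), radius_drift(rk4))
})

test_that("an over-long step triggers the transit-time guard", {
  env <- make_uniform_env(u = 1.5)
  t0 <- env$scenario$grid$times[1]
  pop <- point_population(-5, 36)
  expect_warning(run_simulation(pop, env, drift_config(dt = 6 * 3600),
                                t0, t0 + 86400), "transit")
})

test_that("advance_population performs a single step with beaching", {
  env <- make_uniform_env(v = 0.3)
  g <- env$scenario$grid
  pop <- point_population(-5, 36)
  out <- advance_population(pop, g$times[1], env, drift_config(dt = 1800))
  expect_equal(out$population$lat - pop$lat,
               0.3 * 1800 / 111194.926, tolerance = 1e-6)
  expect_equal(nrow(out$strandings), 0L)
})
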