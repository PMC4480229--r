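# Shared builders for the simulated experiments used across test files.

REF_START <- as.POSIXct("2010-01-26", tz = "UTC")

daily_times <- function(n_days, start = REF_START) {
  seq(start, by = "day", length.out = n_days)
}

# A one-or-more-particle population at given positions.
point_population <- function(lon, lat, handedness = "none") {
  n <- length(lon)
  pop <- data.frame(
    id = seq_len(n) - 1L, lon = lon, lat = lat,
    handedness = rep_len(handedness, n), status = "active",
    strand_time = as.POSIXct(rep(NA_real_, n), tz = "UTC",
                             origin = "1970-01-01"),
    strand_segment = NA_character_, stringsAsFactors = FALSE)
  class(pop) <- c("drift_population", "data.frame")
  pop
}

# Reference domain: Gulf-of-Cadiz/Alboran-like two-basin strait scenario.
reference_domain <- function(n_days = 65, nx = 120, ny = 60,
                             metric_ref_lat = NULL) {
  g <- grid_spec(-10, -1, 34, 38, nx, ny, daily_times(n_days),
                 metric_ref_lat = metric_ref_lat)
  make_scenario("two_basin_strait", g)
}

# Currents of the reference transport experiment: strait-exchange jet plus a
# zonal slope current.
reference_currents <- function(scenario) {
  make_current_field(scenario, "composite", components = list(
    list(kind = "strait_jet", speed = 1),
    list(kind = "slope_current", speed = 0.3)))
}

# Alternating strong/weak south-westerly pulses (2 d + 2 d blocks).
pulsed_westerlies <- function(grid, n_blocks = 10,
                              strong = c(6, 2), weak = c(2.5, 0.3)) {
  t0 <- grid$times[1]
  do.call(rbind, lapply(seq_len(n_blocks) - 1, function(k) {
    s <- t0 + k * 4 * 86400
    rbind(data.frame(start = s, end = s + 2 * 86400,
                     u = strong[1], v = strong[2]),
          data.frame(start = s + 2 * 86400, end = s + 4 * 86400,
                     u = weak[1], v = weak[2]))
  }))
}

# Forward-then-backward source-recovery experiment (two_basin_strait,
# western-margin seeding, pulsed south-westerlies, epoch-mode backtracking to
# the seeding date).  Returns the pieces needed by the assertions.
roundtrip_experiment <- function(n = 500, seed = 99, steady = FALSE) {
  sc <- reference_domain(n_days = 40)
  g <- sc$grid
  cur <- reference_currents(sc)
  eps <- if (steady) {
    data.frame(start = g$times[1], end = g$times[40], u = 4.25, v = 1.15)
  } else pulsed_westerlies(g)
  env <- drift_environment(sc, cur, make_wind_field(g, eps))
  pop <- seed_depth_band(sc, 20, 200, n = n, rng_seed = seed,
                         bbox = c(-9.8, -8.6, 36.6, 38))
  t0 <- g$times[1]
  fw <- run_simulation(pop, env, drift_config(), t0, t0 + 18 * 86400)
  s <- fw$strandings[!is.na(fw$strandings$segment_id), ]
  seg <- names(sort(table(s$segment_id), decreasing = TRUE))[1]
  tt <- as.numeric(s$time[s$segment_id == seg])
  win <- as.POSIXct(range(tt), tz = "UTC", origin = "1970-01-01")
  est <- localize_origin(env, seg, win, n_virtual = n,
                         lookback = min(tt) - as.numeric(t0),
                         mode = "epoch", rng_seed = seed + 1)
  list(scenario = sc, population = pop, forward = fw, segment = seg,
       estimate = est,
       seed_polygon = bounding_polygon(pop$lon, pop$lat),
       jaccard = hull_jaccard(est$hull,
                              bounding_polygon(pop$lon, pop$lat)))
}

# Atlantic-to-Mediterranean transport experiment: persistent westerlies over
# the two-basin strait domain, western-margin seeding.
transport_experiment <- function(n = 2000, seed = 42, days = 60) {
  sc <- reference_domain(n_days = days + 5)
  g <- sc$grid
  cur <- reference_currents(sc)
  w <- make_wind_field(g, data.frame(start = g$times[1],
                                     end = g$times[days + 4], u = 8, v = 1))
  env <- drift_environment(sc, cur, w)
  pop <- seed_depth_band(sc, 20, 200, n = n, rng_seed = seed,
                         bbox = c(-10, -7, 34, 38))
  t0 <- g$times[1]
  run <- run_simulation(pop, env, drift_config(), t0, t0 + days * 86400)
  s <- run$strandings[!is.na(run$strandings$segment_id), ]
  bd <- beaches_df(sc)
  agg <- stats::aggregate(time ~ segment_id, s,
                          function(x) mean(as.numeric(x)))
  agg <- merge(agg, bd, by.x = "segment_id", by.y = "id")
  agg$n <- as.integer(table(s$segment_id)[agg$segment_id])
  keep <- agg$n >= 5
  rho <- stats::cor(rank(agg$lon_mid[keep]), rank(agg$time[keep]),
                    method = "spearman")
  list(scenario = sc, run = run, strandings = s,
       strait_lon = sc$params$strait$lon,
       east_fraction = mean(s$lon > sc$params$strait$lon + 0.2),
       arrival_table = agg[order(agg$lon_mid), ], spearman = rho)
}

# Mirror-symmetry experiment on an f-plane grid: open coast vs its
# reflection, meridionally mirrored winds, swapped handedness.
mirror_experiment <- function(n = 400, seed = 11) {
  g <- grid_spec(-7, -2, 35, 37.5, 100, 50, daily_times(15),
                 metric_ref_lat = 36.25)
  oc <- make_scenario("open_coast", g)
  moc <- mirror_scenario(oc)
  cur <- make_current_field(oc, "uniform", u = 0, v = 0)
  mcur <- make_current_field(moc, "uniform", u = 0, v = 0)
  w <- make_wind_field(g, data.frame(start = g$times[1], end = g$times[15],
                                     u = 4, v = 6))
  mw <- make_wind_field(g, data.frame(start = g$times[1], end = g$times[15],
                                      u = 4, v = -6))
  pop <- seed_depth_band(oc, 20, 200, n = n,
                         handedness_mix = c(right = 1), rng_seed = seed)
  mpop <- pop
  mpop$lat <- g$lat_min + g$lat_max - pop$lat
  mpop$handedness <- "left"
  cfg <- drift_config(handedness_enabled = TRUE, theta_max = 12.5)
  t0 <- g$times[1]; t1 <- t0 + 10 * 86400
  r1 <- run_simulation(pop, drift_environment(oc, cur, w), cfg, t0, t1)
  r2 <- run_simulation(mpop, drift_environment(moc, mcur, mw), cfg, t0, t1)
  list(counts = count_strandings(r1$strandings, oc),
       mirrored_counts = count_strandings(r2$strandings, moc))
}

# Handedness-mix sensitivity under storm onshore winds: all-right vs 50/50
# populations from the same seed.
handedness_experiment <- function(n = 1500, seed = 21) {
  g <- grid_spec(-7, -2, 35, 37.5, 100, 50, daily_times(10))
  oc <- make_scenario("open_coast", g)
  cur <- make_current_field(oc, "uniform", u = 0, v = 0)
  w <- make_wind_field(g, data.frame(start = g$times[1], end = g$times[10],
                                     u = 0, v = 10))
  env <- drift_environment(oc, cur, w)
  cfg <- drift_config(handedness_enabled = TRUE, theta_max = 12.5)
  t0 <- g$times[1]; t1 <- t0 + 5 * 86400
  popR <- seed_depth_band(oc, 20, 200, n = n,
                          handedness_mix = c(right = 1), rng_seed = seed)
  popM <- seed_depth_band(oc, 20, 200, n = n,
                          handedness_mix = c(left = 0.5, right = 0.5),
                          rng_seed = seed)
  rR <- run_simulation(popR, env, cfg, t0, t1)
  rM <- run_simulation(popM, env, cfg, t0, t1)
  cR <- count_strandings(rR$strandings, oc)
  cM <- count_strandings(rM$strandings, oc)
  list(frac_all_right = cR$count / sum(cR$count),
       frac_mixed = cM$count / sum(cM$count))
}
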