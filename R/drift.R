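# The individual-based drift model: windage velocity rule, RK4 stepping with
# beaching detection, and the forward/backward simulation loop.

#' Configuration of the drift rule and integrator
#'
#' The drift velocity of a colony is `u_current + windage * R(theta) * wind`,
#' where `windage` defaults to 0.10 (colonies travel at 10 percent of the
#' 10-m wind speed) and `R(theta)` rotates the wind vector by the
#' handedness-signed sail angle.  With `handedness_enabled = FALSE` (the
#' reference configuration) the rotation is the identity.  When enabled,
#' right-handed colonies deviate clockwise (to the right looking downwind) and
#' left-handed counterclockwise by
#' `theta_eff = theta_max * clip(1 - (|w| - taper)/taper, 0, 1)` degrees:
#' the full `theta_max` (10–15 degrees) up to wind speed `theta_taper_wind`,
#' decaying linearly to zero at twice that speed, reflecting the flattening of
#' the sail angle under intense winds.
#'
#' @param windage dimensionless wind-drag fraction in `[0, 1]`; default 0.10.
#' @param handedness_enabled logical; default `FALSE`.
#' @param theta_max maximal sail angle, degrees; must lie in `[10, 15]` when
#'   handedness is enabled.
#' @param theta_taper_wind wind speed (m/s) above which the sail angle decays
#'   linearly, reaching zero at twice this value; default 10.
#' @param dt integration step, seconds; default 1800.
#' @param integrator `"rk4"` (default) or `"euler"` (for oracle comparisons).
#' @param direction `"forward"` or `"backward"`; backward integration negates
#'   the sampled velocities, runs time in reverse, and disables beaching and
#'   exit (positions clamp to the domain boundary).
#' @param output_stride record trajectory positions every this many steps.
#' @return an object of class `drift_config`.
#' @export
drift_config <- function(windage = 0.10, handedness_enabled = FALSE,
                         theta_max = 12.5, theta_taper_wind = 10,
                         dt = 1800, integrator = c("rk4", "euler"),
                         direction = c("forward", "backward"),
                         output_stride = 24L) {
  integrator <- match.arg(integrator)
  direction <- match.arg(direction)
  if (windage < 0 || windage > 1) stop("windage must lie in [0, 1]")
  if (handedness_enabled && (theta_max < 10 || theta_max > 15))
    stop("theta_max must lie in [10, 15] degrees when handedness is enabled")
  if (!(dt > 0)) stop("dt must be positive")
  if (!(theta_taper_wind > 0)) stop("theta_taper_wind must be positive")
  structure(list(windage = windage, handedness_enabled = handedness_enabled,
                 theta_max = theta_max, theta_taper_wind = theta_taper_wind,
                 dt = dt, integrator = integrator, direction = direction,
                 output_stride = as.integer(output_stride)),
            class = "drift_config")
}

#' Bundle the environment a simulation runs in
#'
#' @param scenario a [make_scenario()] result.
#' @param currents,winds [vector_field()]s on the scenario grid.
#' @return an object of class `drift_environment`.
#' @export
drift_environment <- function(scenario, currents, winds) {
  stopifnot(inherits(scenario, "domain_scenario"),
            inherits(currents, "gridded_vector_field"),
            inherits(winds, "gridded_vector_field"))
  if (currents$grid$nx != scenario$grid$nx ||
      currents$grid$ny != scenario$grid$ny ||
      winds$grid$nx != scenario$grid$nx ||
      winds$grid$ny != scenario$grid$ny)
    stop("currents and winds must live on the scenario grid")
  structure(list(scenario = scenario, currents = currents, winds = winds),
            class = "drift_environment")
}

# Effective sail angle (degrees) at wind speed `speed`.
theta_eff_deg <- function(speed, config) {
  config$theta_max *
    pmin(1, pmax(0, 1 - (speed - config$theta_taper_wind) /
                   config$theta_taper_wind))
}

# Handedness as a rotation sign: +1 left (counterclockwise), -1 right
# (clockwise), 0 none.
hand_sign <- function(handedness) {
  s <- rep(0, length(handedness))
  s[handedness == "left"] <- 1
  s[handedness == "right"] <- -1
  s
}

# Rotate the wind vector by the signed effective sail angle.
rotate_windage <- function(wu, wv, hs, config) {
  if (!config$handedness_enabled || all(hs == 0))
    return(list(u = wu, v = wv))
  spd <- sqrt(wu^2 + wv^2)
  th <- theta_eff_deg(spd, config) * (pi / 180) * hs
  ct <- cos(th); st <- sin(th)
  list(u = wu * ct - wv * st, v = wu * st + wv * ct)
}

#' Drift velocity of colonies at given positions and time
#'
#' Evaluates `u_current + windage * R(theta) * wind` (see [drift_config()]).
#'
#' @param lon,lat positions on ocean cells, decimal degrees.
#' @param t a single timestamp within both fields' time spans.
#' @param currents,winds [vector_field()]s.
#' @param handedness `"none"`, `"left"` or `"right"`, recycled to the number
#'   of positions.
#' @param config a [drift_config()].
#' @return list with numeric vectors `u` and `v` in m/s.
#' @export
drift_velocity <- function(lon, lat, t, currents, winds,
                           handedness = "none", config = drift_config()) {
  stopifnot(length(lon) == length(lat))
  landed <- on_land(currents$mask, currents$grid, lon, lat)
  if (anyNA(landed)) stop("position outside the model domain")
  if (any(landed)) stop("position on a land cell")
  hs <- hand_sign(rep_len(handedness, length(lon)))
  cs <- field_sample(currents, lon, lat, t)
  ws <- field_sample(winds, lon, lat, t)
  wr <- rotate_windage(ws$u, ws$v, hs, config)
  u <- cs$u + config$windage * wr$u
  v <- cs$v + config$windage * wr$v
  if (config$direction == "backward") {
    u <- -u; v <- -v
  }
  list(u = u, v = v)
}

# Sampled drift velocity without validation, on numeric time (hot path).
drift_velocity_num <- function(lon, lat, tsec, env, hs, config, dirsign) {
  cs <- field_sample_num(env$currents, lon, lat, tsec)
  ws <- field_sample_num(env$winds, lon, lat, tsec)
  wr <- rotate_windage(ws$u, ws$v, hs, config)
  list(u = dirsign * (cs$u + config$windage * wr$u),
       v = dirsign * (cs$v + config$windage * wr$v))
}

# One integrator step (RK4 or Euler) from numeric time tsec over dt_step
# seconds of simulated time (calendar time advances dirsign * dt_step).
integrate_step <- function(lon, lat, tsec, dt_step, env, hs, config, dirsign) {
  grd <- env$scenario$grid
  degrate <- function(vel, lat_at) {
    list(dlon = vel$u / lon_m_factor(grd, lat_at),
         dlat = vel$v / M_PER_DEG)
  }
  if (config$integrator == "euler") {
    k1 <- degrate(drift_velocity_num(lon, lat, tsec, env, hs, config,
                                     dirsign), lat)
    return(list(lon = lon + k1$dlon * dt_step, lat = lat + k1$dlat * dt_step))
  }
  h <- dt_step
  t2 <- tsec + dirsign * h / 2
  t3 <- tsec + dirsign * h
  k1 <- degrate(drift_velocity_num(lon, lat, tsec, env, hs, config, dirsign),
                lat)
  p2lon <- lon + k1$dlon * h / 2; p2lat <- lat + k1$dlat * h / 2
  k2 <- degrate(drift_velocity_num(p2lon, p2lat, t2, env, hs, config,
                                   dirsign), p2lat)
  p3lon <- lon + k2$dlon * h / 2; p3lat <- lat + k2$dlat * h / 2
  k3 <- degrate(drift_velocity_num(p3lon, p3lat, t2, env, hs, config,
                                   dirsign), p3lat)
  p4lon <- lon + k3$dlon * h; p4lat <- lat + k3$dlat * h
  k4 <- degrate(drift_velocity_num(p4lon, p4lat, t3, env, hs, config,
                                   dirsign), p4lat)
  list(lon = lon + h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
       lat = lat + h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat))
}

# Locate the land-entry point along the chord old -> new by bisection on the
# land mask; returns fraction f in (0, 1] and the crossing coordinates.
chord_crossing <- function(grid, mask, lon0, lat0, lon1, lat1) {
  flo <- rep(0, length(lon0)); fhi <- rep(1, length(lon0))
  for (it in 1:30) {
    fm <- (flo + fhi) / 2
    plon <- lon0 + fm * (lon1 - lon0)
    plat <- lat0 + fm * (lat1 - lat0)
    landed <- on_land(mask, grid, plon, plat)
    landed[is.na(landed)] <- TRUE
    fhi[landed] <- fm[landed]
    flo[!landed] <- fm[!landed]
  }
  f <- (flo + fhi) / 2
  list(f = f, lon = lon0 + f * (lon1 - lon0), lat = lat0 + f * (lat1 - lat0))
}

#' Run a drift simulation
#'
#' Advances every active colony from `t0` to `t1` with the configured
#' integrator.  Forward runs (`t0 < t1`) detect beaching — a step whose end
#' point falls in a land cell strands the colony at the chord's land-crossing
#' point and time, permanently — and mark colonies leaving the open domain
#' boundary as exited.  Backward runs (`t0 > t1`, `direction = "backward"` in
#' `config`) negate the sampled velocities, run calendar time in reverse, and
#' disable beaching and exit: positions clamp to the boundary so source
#' regions are always produced.
#'
#' @param pop a [seed_depth_band()] population (or any `drift_population`).
#' @param env a [drift_environment()].
#' @param config a [drift_config()]; its `direction` must match the ordering
#'   of `t0` and `t1`.
#' @param t0,t1 start and end timestamps; the environment must cover them.
#' @param verbose print a per-day summary of active/stranded/exited counts.
#' @return an object of class `drift_run` with elements
#'   `trajectories` (`times`, `lon` and `lat` matrices of one row per colony,
#'   `NA` after a colony's terminal event), `strandings` (data frame
#'   `particle_id`, `time`, `lon`, `lat`, `segment_id`), `population` (final
#'   state, with a `clamped` column for backward runs), `counts` (per-step
#'   active/stranded/exited ledger) and `config`.
#' @export
run_simulation <- function(pop, env, config = drift_config(), t0, t1,
                           verbose = FALSE) {
  stopifnot(inherits(pop, "drift_population"),
            inherits(env, "drift_environment"),
            inherits(config, "drift_config"))
  t0 <- as.POSIXct(t0, tz = "UTC"); t1 <- as.POSIXct(t1, tz = "UTC")
  backward <- config$direction == "backward"
  if (!backward && !(t1 > t0))
    stop("forward simulation requires t0 < t1")
  if (backward && !(t1 < t0))
    stop("backward simulation requires t0 > t1")
  tspan <- range(as.numeric(env$currents$grid$times))
  wspan <- range(as.numeric(env$winds$grid$times))
  need <- range(as.numeric(c(t0, t1)))
  if (need[1] < min(tspan[1], wspan[1]) - 1e-3 ||
      need[2] > max(tspan[2], wspan[2]) + 1e-3 ||
      need[1] < wspan[1] - 1e-3 || need[2] > wspan[2] + 1e-3 ||
      need[1] < tspan[1] - 1e-3 || need[2] > tspan[2] + 1e-3)
    stop("environment fields do not cover the simulation window")

  g <- env$scenario$grid
  mask <- env$scenario$land_mask
  n <- nrow(pop)
  lon <- pop$lon; lat <- pop$lat
  status <- ifelse(pop$status == "active", 0L,
                   ifelse(pop$status == "stranded", 1L, 2L))
  hs_all <- hand_sign(pop$handedness)
  clamped <- rep(FALSE, n)

  act0 <- status == 0L
  if (!backward && any(act0)) {
    landed <- on_land(mask, g, lon[act0], lat[act0])
    if (anyNA(landed) || any(landed))
      stop("all active particles must start on ocean cells inside the domain")
  }

  # CFL-like guard: one step should not cross more than one cell at top speed
  smax <- sqrt(max(env$currents$u^2 + env$currents$v^2)) +
    config$windage * sqrt(max(env$winds$u^2 + env$winds$v^2))
  if (smax * config$dt > min(cell_size_m(g)))
    warning(sprintf(paste0("dt = %.0f s exceeds the grid-cell transit time ",
                           "at peak speed %.2f m/s; beaching detection may ",
                           "skip cells"), config$dt, smax))

  dirsign <- if (backward) -1 else 1
  tsec <- as.numeric(t0)
  tend <- as.numeric(t1)
  total <- abs(tend - tsec)
  nsteps <- ceiling(total / config$dt - 1e-9)
  nsnap <- floor(nsteps / config$output_stride) + 2L
  traj_lon <- matrix(NA_real_, n, nsnap)
  traj_lat <- matrix(NA_real_, n, nsnap)
  traj_t <- rep(NA_real_, nsnap)
  snap <- function(col, tt) {
    a <- status == 0L
    traj_lon[a, col] <<- lon[a]; traj_lat[a, col] <<- lat[a]
    traj_t[col] <<- tt
  }
  snap(1L, tsec)
  isnap <- 1L

  sp <- st <- slon <- slat <- list()   # stranding accumulators
  counts <- matrix(0L, nsteps, 3L)
  day_done <- 0

  for (step in seq_len(nsteps)) {
    dt_step <- min(config$dt, abs(tend - tsec))
    a <- which(status == 0L)
    if (length(a)) {
    np <- integrate_step(lon[a], lat[a], tsec, dt_step, env, hs_all[a],
                         config, dirsign)
    tnew <- tsec + dirsign * dt_step
    out <- np$lon < g$lon_min | np$lon > g$lon_max |
           np$lat < g$lat_min | np$lat > g$lat_max
    if (any(out)) {
      clon <- pmin(pmax(np$lon[out], g$lon_min), g$lon_max)
      clat <- pmin(pmax(np$lat[out], g$lat_min), g$lat_max)
      if (backward) {
        np$lon[out] <- clon; np$lat[out] <- clat
        clamped[a[out]] <- TRUE
      } else {
        status[a[out]] <- 2L
        lon[a[out]] <- clon; lat[a[out]] <- clat
      }
    }
    alive <- which(!out | backward)
    if (length(alive)) {
      ia <- a[alive]
      landed <- on_land(mask, g, np$lon[alive], np$lat[alive])
      landed[is.na(landed)] <- FALSE
      hit <- which(landed)
      if (length(hit)) {
        ih <- ia[hit]
        if (backward) {
          # beaching disabled: stall at the pre-step position
          clamped[ih] <- TRUE
          np$lon[alive][hit] <- lon[ih]; np$lat[alive][hit] <- lat[ih]
        } else {
          cx <- chord_crossing(g, mask, lon[ih], lat[ih],
                               np$lon[alive][hit], np$lat[alive][hit])
          status[ih] <- 1L
          lon[ih] <- cx$lon; lat[ih] <- cx$lat
          sp[[length(sp) + 1L]] <- pop$id[ih]
          st[[length(st) + 1L]] <- tsec + dirsign * cx$f * dt_step
          slon[[length(slon) + 1L]] <- cx$lon
          slat[[length(slat) + 1L]] <- cx$lat
        }
      }
      ok <- which(status[ia] == 0L)
      lon[ia[ok]] <- np$lon[alive][ok]
      lat[ia[ok]] <- np$lat[alive][ok]
    }
    }
    tsec <- tsec + dirsign * dt_step
    counts[step, ] <- c(sum(status == 0L), sum(status == 1L),
                        sum(status == 2L))
    if (step %% config$output_stride == 0L) {
      isnap <- isnap + 1L
      snap(isnap, tsec)
    }
    if (verbose) {
      day <- floor(abs(tsec - as.numeric(t0)) / 86400)
      if (day > day_done) {
        day_done <- day
        message(sprintf("day %3d: %d active, %d stranded, %d exited", day,
                        counts[step, 1], counts[step, 2], counts[step, 3]))
      }
    }
  }
  if (traj_t[isnap] != tsec) {
    isnap <- isnap + 1L
    snap(isnap, tsec)
  }
  traj_lon <- traj_lon[, seq_len(isnap), drop = FALSE]
  traj_lat <- traj_lat[, seq_len(isnap), drop = FALSE]
  traj_t <- traj_t[seq_len(isnap)]

  strand <- data.frame(
    particle_id = if (length(sp)) unlist(sp) else integer(0),
    time = as.POSIXct(if (length(st)) unlist(st) else numeric(0),
                      tz = "UTC", origin = "1970-01-01"),
    lon = if (length(slon)) unlist(slon) else numeric(0),
    lat = if (length(slat)) unlist(slat) else numeric(0),
    stringsAsFactors = FALSE
  )
  strand$segment_id <- if (nrow(strand))
    assign_to_beach(strand, env$scenario) else character(0)

  newpop <- pop
  newpop$lon <- lon; newpop$lat <- lat
  newpop$status <- c("active", "stranded", "exited")[status + 1L]
  if (nrow(strand)) {
    m <- match(strand$particle_id, newpop$id)
    newpop$strand_time[m] <- strand$time
    newpop$strand_segment[m] <- strand$segment_id
  }
  if (backward) newpop$clamped <- clamped

  structure(list(
    trajectories = list(times = as.POSIXct(traj_t, tz = "UTC",
                                           origin = "1970-01-01"),
                        lon = traj_lon, lat = traj_lat),
    strandings = strand,
    population = newpop,
    counts = data.frame(step = seq_len(nsteps),
                        n_active = counts[, 1], n_stranded = counts[, 2],
                        n_exited = counts[, 3]),
    config = config, t0 = t0, t1 = t1
  ), class = "drift_run")
}

#' @export
print.drift_run <- function(x, ...) {
  fin <- table(factor(x$population$status,
                      levels = c("active", "stranded", "exited")))
  cat(sprintf("drift_run: %d colonies, %s -> %s (%s)\n",
              nrow(x$population), format(x$t0, "%Y-%m-%d %H:%M"),
              format(x$t1, "%Y-%m-%d %H:%M"), x$config$direction))
  cat(sprintf("  final: %d active, %d stranded, %d exited; %d strandings\n",
              fin["active"], fin["stranded"], fin["exited"],
              nrow(x$strandings)))
  invisible(x)
}

#' Advance a population by a single time step
#'
#' Convenience single-step wrapper around the simulation core: steps every
#' active colony by `config$dt` from `t`, applying beaching and exit rules.
#'
#' @param pop a `drift_population`.
#' @param t the current timestamp.
#' @param env a [drift_environment()].
#' @param config a [drift_config()].
#' @return list with the updated `population` and the new `strandings`
#'   records of this step.
#' @export
advance_population <- function(pop, t, env, config = drift_config()) {
  t <- as.POSIXct(t, tz = "UTC")
  dirsign <- if (config$direction == "backward") -1 else 1
  run <- run_simulation(pop, env, config, t, t + dirsign * config$dt)
  list(population = run$population, strandings = run$strandings)
}
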