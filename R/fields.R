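# Synthetic current and wind fields on scenario grids.

#' Generate an idealized surface-current field for a scenario
#'
#' Available kinds:
#'
#' * `"uniform"` — constant `(u, v)` over all ocean cells.
#' * `"gyre"` — solid-body rotation inside radius `radius_km` (speed grows
#'   linearly to `peak` at the rim) with exponential decay outside
#'   (e-folding `decay_km`); `rotation` selects anticyclonic (clockwise, the
#'   Alboran gyre sense) or cyclonic.
#' * `"strait_jet"` — a zonal jet with a Gaussian latitudinal profile centred
#'   on the strait (or `lat_center`), carrying through-strait transport of the
#'   sign of `speed` (positive eastward, the Gibraltar inflow analog).
#' * `"slope_current"` — a zonal current that decays exponentially offshore
#'   (e-folding `efold_km` from the coast), the slope-current analog.
#' * `"composite"` — the exact cell-wise sum of constituent fields given as
#'   `components = list(list(kind = ..., <params>), ...)`.
#'
#' All fields are steady (one time slice, valid over the grid's time span),
#' zero on land, and capped at 3 m/s peak speed.
#'
#' @param scenario a [make_scenario()] result.
#' @param kind one of the field kinds above.
#' @param ... kind-specific parameters (see Details).
#' @return a [vector_field()] on the scenario grid, masked by the scenario's
#'   land mask.
#' @export
make_current_field <- function(scenario,
                               kind = c("uniform", "gyre", "strait_jet",
                                        "slope_current", "composite"),
                               ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(scenario, "domain_scenario"))
  p <- list(...)
  g <- scenario$grid
  uv <- current_components(scenario, kind, p)
  uv$u[scenario$land_mask] <- 0
  uv$v[scenario$land_mask] <- 0
  vector_field(g, uv$u, uv$v, mask = scenario$land_mask)
}

current_components <- function(scenario, kind, p) {
  g <- scenario$grid
  ny <- g$ny; nx <- g$nx
  cap <- function(s, what) {
    if (abs(s) > 3) stop(sprintf("%s exceeds the 3 m/s speed cap", what))
    s
  }
  if (kind == "uniform") {
    u0 <- cap(p$u %||% 0, "u"); v0 <- cap(p$v %||% 0, "v")
    return(list(u = matrix(u0, ny, nx), v = matrix(v0, ny, nx)))
  }
  if (kind == "gyre") {
    lon0 <- p$center_lon %||% mean(g$lon)
    lat0 <- p$center_lat %||% mean(g$lat)
    peak <- cap(p$peak %||% 0.5, "peak")
    R <- (p$radius_km %||% 30) * 1000
    decay <- (p$decay_km %||% ((p$radius_km %||% 30) / 8)) * 1000
    rot <- match.arg(p$rotation %||% "anticyclonic",
                     c("anticyclonic", "cyclonic"))
    nc <- nearest_cell(g, lon0, lat0)
    if (!nc$inside || scenario$land_mask[nc$j, nc$i])
      stop("gyre center must lie on an ocean cell")
    X <- outer(rep(1, ny), g$lon - lon0) * m_per_deg_lon(lat0)
    Y <- outer(g$lat - lat0, rep(1, nx)) * M_PER_DEG
    r <- sqrt(X^2 + Y^2)
    s <- ifelse(r <= R, peak * r / R, peak * exp(-(r - R) / decay))
    sgn <- if (rot == "anticyclonic") -1 else 1   # counterclockwise positive
    rr <- pmax(r, 1e-9)
    return(list(u = sgn * (-Y / rr) * s, v = sgn * (X / rr) * s))
  }
  if (kind == "strait_jet") {
    # Aperture (strait-exchange) flow from a streamfunction
    # psi = (Q/2) tanh(2 (y - y0) / W(x)): a zonal jet of transport Q that
    # narrows from the basin scale to the gap width at the strait, so the
    # flow converges into the strait from the west and fans out east of it
    # (the "suction" feeding the inflow).  u = Q sech^2 / W peaks at `speed`
    # in the gap; v = -dpsi/dx is the convergent/divergent component.
    speed <- cap(p$speed %||% 1, "speed")
    st <- scenario$params$strait
    lat_c <- p$lat_center %||% if (!is.null(st)) mean(st$lat_range)
             else mean(g$lat)
    W0 <- (p$width_km %||% if (!is.null(st))
      diff(st$lat_range) * M_PER_DEG / 1000 else 30) * 1000
    lon_b <- p$strait_lon %||% if (!is.null(st)) st$lon else mean(g$lon)
    Wb <- (g$lat_max - g$lat_min) * M_PER_DEG         # basin-scale width
    reach_m <- (p$reach_km %||%
      ((g$lon_max - g$lon_min) * m_per_deg_lon(lat_c) / 1000 / 3)) * 1000
    Q <- speed * W0
    X <- outer(rep(1, ny), (g$lon - lon_b) * m_per_deg_lon(lat_c))
    Y <- outer((g$lat - lat_c) * M_PER_DEG, rep(1, nx))
    ramp <- pmin(1, abs(X) / reach_m)
    W <- W0 + (Wb - W0) * ramp
    dWdX <- (Wb - W0) / reach_m * sign(X) * (abs(X) < reach_m)
    sech2 <- 1 / cosh(2 * Y / W)^2
    return(list(u = Q * sech2 / W, v = Q * sech2 * Y * dWdX / W^2))
  }
  if (kind == "slope_current") {
    speed <- cap(p$speed %||% 0.3, "speed")
    efold_m <- (p$efold_km %||% 30) * 1000
    dist_m <- land_distance_cells(scenario$land_mask) *
      min(cell_size_m(g))
    u <- speed * exp(-dist_m / efold_m)
    return(list(u = u, v = matrix(0, ny, nx)))
  }
  # composite: exact sum of constituent components
  comps <- p$components
  if (is.null(comps) || !length(comps))
    stop("composite field needs a non-empty 'components' list")
  u <- matrix(0, ny, nx); v <- matrix(0, ny, nx)
  for (cmp in comps) {
    ck <- match.arg(cmp$kind, c("uniform", "gyre", "strait_jet",
                                "slope_current"))
    uv <- current_components(scenario, ck, cmp[setdiff(names(cmp), "kind")])
    u <- u + uv$u; v <- v + uv$v
  }
  list(u = u, v = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a wind field from a list of episodes
#'
#' Each episode is a spell of spatially uniform wind: the field equals the
#' episode's `(u, v)` at every snapshot falling inside `[start, end)` and is
#' zero outside all episodes.  Episodes must not overlap and wind speeds are
#' capped at 40 m/s.  An optional linear spatial `gradient` (per-degree
#' derivatives about the domain centre) superimposes large-scale shear.
#'
#' @param grid a [grid_spec()]; the wind is defined at its snapshots.
#' @param episodes a data frame with columns `start`, `end` (timestamps) and
#'   `u`, `v` (m/s), or a list of lists with those elements; may be empty.
#' @param gradient optional list with any of `du_dlon`, `du_dlat`, `dv_dlon`,
#'   `dv_dlat` (m/s per degree).
#' @return a [vector_field()] with one slice per snapshot and no land mask
#'   (winds are defined over land as well).
#' @export
make_wind_field <- function(grid, episodes = NULL, gradient = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  ep <- normalize_episodes(episodes)
  nt <- length(grid$times)
  ny <- grid$ny; nx <- grid$nx
  u <- array(0, dim = c(ny, nx, nt))
  v <- array(0, dim = c(ny, nx, nt))
  tsec <- as.numeric(grid$times)
  gu <- matrix(0, ny, nx); gv <- matrix(0, ny, nx)
  if (!is.null(gradient)) {
    dlon <- outer(rep(1, ny), grid$lon - mean(grid$lon))
    dlat <- outer(grid$lat - mean(grid$lat), rep(1, nx))
    gu <- (gradient$du_dlon %||% 0) * dlon + (gradient$du_dlat %||% 0) * dlat
    gv <- (gradient$dv_dlon %||% 0) * dlon + (gradient$dv_dlat %||% 0) * dlat
  }
  if (nrow(ep)) {
    for (k in seq_len(nt)) {
      hit <- which(tsec[k] >= ep$start & tsec[k] < ep$end)
      if (length(hit)) {
        u[, , k] <- ep$u[hit[1]] + gu
        v[, , k] <- ep$v[hit[1]] + gv
      }
    }
  }
  vector_field(grid, u, v)
}

normalize_episodes <- function(episodes) {
  if (is.null(episodes) || (is.data.frame(episodes) && !nrow(episodes)) ||
      (!is.data.frame(episodes) && !length(episodes)))
    return(data.frame(start = numeric(0), end = numeric(0),
                      u = numeric(0), v = numeric(0)))
  if (!is.data.frame(episodes))
    episodes <- do.call(rbind, lapply(episodes, function(e)
      data.frame(start = as.POSIXct(e$start, tz = "UTC"),
                 end = as.POSIXct(e$end, tz = "UTC"),
                 u = e$u, v = e$v)))
  ep <- data.frame(start = as.numeric(as.POSIXct(episodes$start, tz = "UTC")),
                   end = as.numeric(as.POSIXct(episodes$end, tz = "UTC")),
                   u = episodes$u, v = episodes$v)
  if (any(ep$end <= ep$start)) stop("episode end must be after its start")
  if (any(sqrt(ep$u^2 + ep$v^2) > 40))
    stop("episode wind speed exceeds the 40 m/s cap")
  ep <- ep[order(ep$start), , drop = FALSE]
  if (nrow(ep) > 1L && any(ep$end[-nrow(ep)] > ep$start[-1] + 1e-9))
    stop("wind episodes must not overlap")
  ep
}
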