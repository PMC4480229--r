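# Regular geographic grids and time-varying gridded vector fields.
#
# All coordinates are decimal degrees on a regular lon/lat grid.  Metric
# conversions use a local equirectangular approximation with cos(latitude)
# scaling; for domains spanning a few degrees the error is far below the grid
# resolution.

EARTH_RADIUS_M <- 6371000
M_PER_DEG <- EARTH_RADIUS_M * pi / 180

#' Metres per degree of longitude at a given latitude
#' @param lat latitude in decimal degrees
#' @return metres spanned by one degree of longitude
#' @keywords internal
m_per_deg_lon <- function(lat) M_PER_DEG * cos(lat * pi / 180)

# Longitude metric factor respecting the grid's metric convention.
lon_m_factor <- function(grid, lat) {
  if (!is.null(grid$metric_ref_lat))
    M_PER_DEG * cos(grid$metric_ref_lat * pi / 180)
  else M_PER_DEG * cos(lat * pi / 180)
}

#' Define a regular longitude-latitude grid with a time axis
#'
#' The grid covers `[lon_min, lon_max] x [lat_min, lat_max]` with `nx` by `ny`
#' equal cells; cell-centre coordinates are stored in `$lon` and `$lat`.  The
#' time axis carries the snapshots at which gridded fields are defined; field
#' values between snapshots are interpolated linearly in time.
#'
#' @param lon_min,lon_max,lat_min,lat_max domain edges, decimal degrees.
#' @param nx,ny number of cells in longitude and latitude (at least 2 each).
#' @param times timestamps (POSIXct, or anything `as.POSIXct` accepts; UTC),
#'   strictly increasing.
#' @param metric_ref_lat optional reference latitude (degrees) for the
#'   longitude metric.  `NULL` (default) uses the local `cos(lat)` at each
#'   position (spherical metric); a numeric value fixes `cos(metric_ref_lat)`
#'   everywhere — the f-plane idealization, under which the dynamics are
#'   exactly symmetric about a zonal midline (used by the mirror-symmetry
#'   audit).
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(-10, -1, 34, 38, nx = 90, ny = 40,
#'                times = seq(as.POSIXct("2010-01-26", tz = "UTC"),
#'                            by = "day", length.out = 10))
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, nx, ny, times,
                      metric_ref_lat = NULL) {
  if (!is.numeric(lon_min) || !is.numeric(lon_max) ||
      !is.numeric(lat_min) || !is.numeric(lat_max))
    stop("grid bounds must be numeric degrees")
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("grid bounds must satisfy lon_min < lon_max and lat_min < lat_max")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L)
    stop("nx and ny must be at least 2")
  times <- as.POSIXct(times, tz = "UTC")
  if (length(times) < 1L || anyNA(times))
    stop("times must be a non-empty vector of valid timestamps")
  if (is.unsorted(as.numeric(times), strictly = TRUE))
    stop("times must be strictly increasing")
  dlon <- (lon_max - lon_min) / nx
  dlat <- (lat_max - lat_min) / ny
  structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    nx = nx, ny = ny, dlon = dlon, dlat = dlat,
    lon = lon_min + (seq_len(nx) - 0.5) * dlon,
    lat = lat_min + (seq_len(ny) - 0.5) * dlat,
    times = times,
    metric_ref_lat = metric_ref_lat
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
              x$nx, x$ny, x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  cat(sprintf("  cell size %.4f x %.4f deg (~%.1f x %.1f km at mid-latitude)\n",
              x$dlon, x$dlat,
              x$dlon * m_per_deg_lon(mean(x$lat)) / 1000,
              x$dlat * M_PER_DEG / 1000))
  cat(sprintf("  %d time steps, %s .. %s UTC\n", length(x$times),
              format(min(x$times), "%Y-%m-%d %H:%M"),
              format(max(x$times), "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Cell dimensions in metres at the domain mid-latitude
#' @keywords internal
cell_size_m <- function(grid) {
  c(dx = grid$dlon * m_per_deg_lon(mean(grid$lat)), dy = grid$dlat * M_PER_DEG)
}

#' Construct a time-varying vector field on a grid
#'
#' Stores the east (`u`) and north (`v`) components, in m/s, of a gridded flow
#' (surface current or 10-m wind) on the cell centres of `grid`.  Arrays are
#' dimensioned `(ny, nx, nt)` where `nt` is either `length(grid$times)` (one
#' slice per snapshot) or 1 (a steady field, valid over the grid's whole time
#' span).  Land cells (where `mask` is `TRUE`) carry zero velocity; sampling
#' near land renormalizes the bilinear weights over ocean cells so the flow
#' stays continuous without spurious onshore pull.
#'
#' @param grid a [grid_spec()].
#' @param u,v numeric matrices `(ny, nx)` (steady) or arrays `(ny, nx, nt)`.
#' @param mask logical `(ny, nx)` matrix, `TRUE` on land; default all ocean.
#' @return an object of class `gridded_vector_field`.
#' @export
vector_field <- function(grid, u, v, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  to3d <- function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    if (length(dim(a)) != 3L) stop("u and v must be (ny, nx) or (ny, nx, nt)")
    a
  }
  u <- to3d(u); v <- to3d(v)
  nt <- dim(u)[3]
  if (!identical(dim(u), dim(v))) stop("u and v must have identical dimensions")
  if (dim(u)[1] != grid$ny || dim(u)[2] != grid$nx)
    stop("field dimensions do not match the grid")
  if (nt != 1L && nt != length(grid$times))
    stop("third dimension must be 1 (steady) or length(grid$times)")
  if (is.null(mask)) mask <- matrix(FALSE, grid$ny, grid$nx)
  if (!is.logical(mask) || !identical(dim(mask), c(grid$ny, grid$nx)))
    stop("mask must be a logical (ny, nx) matrix")
  # enforce zero velocity on land, finite values on ocean
  for (k in seq_len(nt)) {
    uk <- u[, , k]; vk <- v[, , k]
    if (any(!is.finite(uk[!mask])) || any(!is.finite(vk[!mask])))
      stop("non-finite velocities on ocean cells")
    uk[mask] <- 0; vk[mask] <- 0
    u[, , k] <- uk; v[, , k] <- vk
  }
  structure(list(grid = grid, u = u, v = v, mask = mask),
            class = "gridded_vector_field")
}

#' @export
print.gridded_vector_field <- function(x, ...) {
  cat(sprintf("gridded_vector_field: %d x %d x %d (lat x lon x time)\n",
              dim(x$u)[1], dim(x$u)[2], dim(x$u)[3]))
  cat(sprintf("  max speed %.3f m/s, %d land cells\n",
              sqrt(max(x$u^2 + x$v^2)), sum(x$mask)))
  invisible(x)
}

# Containing-cell indices of positions; inside = within the domain edges.
nearest_cell <- function(grid, lon, lat) {
  i <- floor((lon - grid$lon_min) / grid$dlon) + 1
  j <- floor((lat - grid$lat_min) / grid$dlat) + 1
  i <- pmin(pmax(i, 1), grid$nx)   # positions exactly on the outer edge
  j <- pmin(pmax(j, 1), grid$ny)
  inside <- lon >= grid$lon_min & lon <= grid$lon_max &
            lat >= grid$lat_min & lat <= grid$lat_max
  list(i = as.integer(i), j = as.integer(j), inside = inside)
}

# TRUE where the containing cell is land (NA outside the domain).
on_land <- function(mask, grid, lon, lat) {
  nc <- nearest_cell(grid, lon, lat)
  out <- rep(NA, length(lon))
  out[nc$inside] <- mask[cbind(nc$j[nc$inside], nc$i[nc$inside])]
  out
}

#' Sample a gridded vector field at arbitrary positions and one time
#'
#' Bilinear interpolation in space and linear interpolation in time.  Corner
#' weights falling on land cells are set to zero and the remaining weights
#' renormalized; if all four corners are land the sampled velocity is zero.
#'
#' @param field a [vector_field()].
#' @param lon,lat positions (vectors of equal length), decimal degrees.
#' @param t a single timestamp within the field's time span.
#' @return list with numeric vectors `u` and `v` (m/s).
#' @export
field_sample <- function(field, lon, lat, t) {
  tsec <- as.numeric(as.POSIXct(t, tz = "UTC"))
  field_sample_num(field, lon, lat, tsec)
}

# Hot path: t already numeric seconds since epoch.
field_sample_num <- function(field, lon, lat, tsec) {
  g <- field$grid
  ts <- as.numeric(g$times)
  nt_grid <- length(ts)
  if (tsec < ts[1] - 1e-3 || tsec > ts[nt_grid] + 1e-3)
    stop("sample time outside the field's time span")
  nt_arr <- dim(field$u)[3]
  if (nt_arr == 1L) {
    k <- 1L; wt <- 0
  } else {
    k <- findInterval(tsec, ts)
    k <- min(max(k, 1L), nt_grid - 1L)
    wt <- (tsec - ts[k]) / (ts[k + 1L] - ts[k])
    wt <- min(max(wt, 0), 1)
  }
  nx <- g$nx; ny <- g$ny
  i <- findInterval(lon, g$lon); i <- pmin(pmax(i, 1L), nx - 1L)
  j <- findInterval(lat, g$lat); j <- pmin(pmax(j, 1L), ny - 1L)
  wx <- pmin(pmax((lon - g$lon[i]) / g$dlon, 0), 1)
  wy <- pmin(pmax((lat - g$lat[j]) / g$dlat, 0), 1)
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy;       w11 <- wx * wy
  sea <- !field$mask
  w00 <- w00 * sea[cbind(j, i)]
  w10 <- w10 * sea[cbind(j, i + 1L)]
  w01 <- w01 * sea[cbind(j + 1L, i)]
  w11 <- w11 * sea[cbind(j + 1L, i + 1L)]
  wsum <- w00 + w10 + w01 + w11
  inv <- ifelse(wsum > 0, 1 / wsum, 0)
  base00 <- (i - 1L) * ny + j
  gather <- function(a, kk) {
    off <- (kk - 1L) * ny * nx
    (a[off + base00]           * w00 +
     a[off + base00 + ny]      * w10 +
     a[off + base00 + 1L]      * w01 +
     a[off + base00 + ny + 1L] * w11) * inv
  }
  u <- gather(field$u, k); v <- gather(field$v, k)
  if (nt_arr > 1L && wt > 0) {
    u <- (1 - wt) * u + wt * gather(field$u, k + 1L)
    v <- (1 - wt) * v + wt * gather(field$v, k + 1L)
  }
  list(u = u, v = v)
}

# Evaluate a seed-preserving expression: sets the RNG state, restores it after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
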