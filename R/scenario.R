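# Idealized coastal domains: land masks, bathymetry and beach segments.

#' Build an idealized coastal domain scenario
#'
#' Three presets provide the geometric ingredients of the Gulf-of-Cadiz /
#' Alboran drift problem without any external data:
#'
#' * `"two_basin_strait"` — two ocean basins separated by a central landmass
#'   pierced by one narrow strait (a Gibraltar analog), with land along the
#'   northern and southern edges and a closed eastern end.
#' * `"open_coast"` — land along the northern edge only (an Atlantic open
#'   coast analog).
#' * `"single_gyre_basin"` — a fully enclosed rectangular basin (an Alboran
#'   basin analog) suitable for gyre retention experiments.
#'
#' Bathymetry follows an exponential offshore profile: 20 m one cell off the
#' coast, 200 m at `shelf_cells` cells offshore, capped at `depth_max`, so a
#' 20–200 m seeding band exists along every coast by construction.  Beach
#' segments are derived as maximal straight runs of land–ocean boundary faces,
#' subdivided into chunks of at most `beach_max_cells` cells, and labelled
#' west to east (`B01`, `B02`, ...), which makes west-to-east arrival ordering
#' well defined.
#'
#' @param preset one of `"two_basin_strait"`, `"open_coast"`,
#'   `"single_gyre_basin"`.
#' @param grid a [grid_spec()].
#' @param shelf_cells distance offshore (in cells) of the 200 m isobath.
#' @param depth_max maximum basin depth, metres.
#' @param beach_max_cells maximum beach segment length in coastal cells.
#' @return an object of class `domain_scenario` with elements `grid`,
#'   `bathymetry` (metres, positive down, 0 on land), `land_mask`, `beaches`
#'   (list of beach segments ordered west to east) and `params`.
#' @examples
#' g <- grid_spec(-10, -1, 34, 38, 120, 60,
#'                times = as.POSIXct("2010-01-26", tz = "UTC"))
#' sc <- make_scenario("two_basin_strait", g)
#' @export
make_scenario <- function(preset = c("two_basin_strait", "open_coast",
                                     "single_gyre_basin"),
                          grid, shelf_cells = 8L, depth_max = 600,
                          beach_max_cells = 15L) {
  preset <- match.arg(preset)
  stopifnot(inherits(grid, "grid_spec"))
  shelf_cells <- max(2L, as.integer(shelf_cells))
  nx <- grid$nx; ny <- grid$ny
  land <- matrix(FALSE, ny, nx)
  nland <- max(2L, round(0.12 * ny))
  strait <- NULL

  if (preset == "open_coast") {
    land[(ny - nland + 1L):ny, ] <- TRUE
  } else if (preset == "single_gyre_basin") {
    nlx <- max(2L, round(0.08 * nx))
    land[c(seq_len(nland), (ny - nland + 1L):ny), ] <- TRUE
    land[, c(seq_len(nlx), (nx - nlx + 1L):nx)] <- TRUE
  } else { # two_basin_strait
    land[(ny - nland + 1L):ny, ] <- TRUE            # northern landmass
    land[seq_len(nland), ] <- TRUE                  # southern landmass
    ewall <- max(2L, round(0.04 * nx))
    land[, (nx - ewall + 1L):nx] <- TRUE            # closed eastern end
    bw <- max(2L, round(0.03 * nx))                 # barrier width, cells
    ic <- as.integer(round(nx / 2))
    bcols <- (ic - floor(bw / 2)):(ic - floor(bw / 2) + bw - 1L)
    ocean_rows <- (nland + 1L):(ny - nland)
    ngap <- as.integer(round(0.25 * length(ocean_rows)))
    if (ngap < 2L)
      stop("grid too coarse to resolve the strait (gap would be < 2 cells)")
    # the strait abuts the northern landmass: its northern shore is the
    # continuous northern coast, as at Gibraltar
    gap <- ocean_rows[(length(ocean_rows) - ngap + 1L):length(ocean_rows)]
    land[setdiff(ocean_rows, gap), bcols] <- TRUE
    strait <- list(
      lon = mean(grid$lon[bcols]),
      lon_range = range(grid$lon[bcols]),
      lat_range = range(grid$lat[gap]),
      gap_cells = ngap
    )
  }

  dist <- land_distance_cells(land)
  depth <- matrix(0, ny, nx)
  sea <- !land
  depth[sea] <- pmin(depth_max,
                     20 * exp(log(10) * (dist[sea] - 1) / (shelf_cells - 1)))
  beaches <- derive_beaches(grid, land, beach_max_cells)

  structure(list(
    grid = grid, bathymetry = depth, land_mask = land, beaches = beaches,
    preset = preset,
    params = list(shelf_cells = shelf_cells, depth_max = depth_max,
                  beach_max_cells = beach_max_cells, coast_cells = nland,
                  strait = strait)
  ), class = "domain_scenario")
}

#' @export
print.domain_scenario <- function(x, ...) {
  cat(sprintf("domain_scenario '%s': %d x %d cells, %d beaches, %.0f%% land\n",
              x$preset, x$grid$nx, x$grid$ny, length(x$beaches),
              100 * mean(x$land_mask)))
  if (!is.null(x$params$strait))
    cat(sprintf("  strait at lon %.3f, gap %d cells\n",
                x$params$strait$lon, x$params$strait$gap_cells))
  invisible(x)
}

# Distance (in cells) from every cell to the nearest land cell, by iterative
# 8-neighbour relaxation (chamfer metric: 1 axial, sqrt(2) diagonal).
land_distance_cells <- function(land) {
  ny <- nrow(land); nx <- ncol(land)
  if (!any(land)) stop("scenario has no land cells")
  d <- matrix(Inf, ny, nx)
  d[land] <- 0
  s2 <- sqrt(2)
  repeat {
    d0 <- d
    d[-1, ]  <- pmin(d[-1, ],  d0[-ny, ] + 1)       # from south
    d[-ny, ] <- pmin(d[-ny, ], d0[-1, ] + 1)        # from north
    d[, -1]  <- pmin(d[, -1],  d0[, -nx] + 1)       # from west
    d[, -nx] <- pmin(d[, -nx], d0[, -1] + 1)        # from east
    d[-1, -1]   <- pmin(d[-1, -1],   d0[-ny, -nx] + s2)
    d[-1, -nx]  <- pmin(d[-1, -nx],  d0[-ny, -1] + s2)
    d[-ny, -1]  <- pmin(d[-ny, -1],  d0[-1, -nx] + s2)
    d[-ny, -nx] <- pmin(d[-ny, -nx], d0[-1, -1] + s2)
    if (all(d == d0)) break
  }
  d
}

# Derive beach segments from a land mask: collect land-ocean boundary faces by
# orientation, group them into maximal straight runs, split long runs, order
# all segments west to east and assign sequential ids.
derive_beaches <- function(grid, land, beach_max_cells = 15L) {
  ny <- nrow(land); nx <- ncol(land)
  ocean <- !land
  shift <- function(m, dj, di) {
    out <- matrix(FALSE, ny, nx)
    js <- seq_len(ny) + dj; is <- seq_len(nx) + di
    keep_j <- js >= 1 & js <= ny; keep_i <- is >= 1 & is <= nx
    out[keep_j, keep_i] <- m[js[keep_j], is[keep_i]]
    out
  }
  faces <- list(
    south = list(m = land & shift(ocean, -1, 0), exposure = 180),
    north = list(m = land & shift(ocean,  1, 0), exposure = 0),
    east  = list(m = land & shift(ocean,  0, 1), exposure = 90),
    west  = list(m = land & shift(ocean,  0, -1), exposure = 270)
  )
  segs <- list()
  chunk <- function(idx, maxlen) {
    npieces <- ceiling(length(idx) / maxlen)
    split(idx, rep(seq_len(npieces), each = ceiling(length(idx) / npieces),
                   length.out = length(idx)))
  }
  for (orient in names(faces)) {
    fm <- faces[[orient]]$m
    expo <- faces[[orient]]$exposure
    horizontal <- orient %in% c("south", "north")
    along <- if (horizontal) which(rowSums(fm) > 0) else which(colSums(fm) > 0)
    for (a in along) {
      cells <- if (horizontal) which(fm[a, ]) else which(fm[, a])
      runs <- split(cells, cumsum(c(1, diff(cells) != 1)))
      for (run in runs) {
        for (piece in chunk(run, beach_max_cells)) {
          i1 <- min(piece); i2 <- max(piece)
          if (horizontal) {
            blat <- grid$lat_min + (a - if (orient == "south") 1L else 0L) *
              grid$dlat
            verts <- cbind(lon = grid$lon_min + c(i1 - 1L, i2) * grid$dlon,
                           lat = c(blat, blat))
            cells_df <- data.frame(i = piece, j = a)
          } else {
            blon <- grid$lon_min + (a - if (orient == "west") 1L else 0L) *
              grid$dlon
            verts <- cbind(lon = c(blon, blon),
                           lat = grid$lat_min + c(i1 - 1L, i2) * grid$dlat)
            cells_df <- data.frame(i = a, j = piece)
          }
          segs[[length(segs) + 1L]] <- list(
            vertices = verts,
            length_m = sum(geosphere::distGeo(verts[-nrow(verts), , drop = FALSE],
                                              verts[-1, , drop = FALSE])),
            exposure_deg = expo,
            orientation = orient,
            cells = cells_df
          )
        }
      }
    }
  }
  if (length(segs) == 0L) stop("land mask has no land-ocean boundary")
  mids <- t(vapply(segs, function(s) colMeans(s$vertices), numeric(2)))
  ord <- order(mids[, 1], mids[, 2])
  segs <- segs[ord]
  for (k in seq_along(segs)) {
    segs[[k]]$id <- sprintf("B%02d", k)
    segs[[k]]$lon_mid <- mean(segs[[k]]$vertices[, 1])
    segs[[k]]$lat_mid <- mean(segs[[k]]$vertices[, 2])
  }
  names(segs) <- vapply(segs, `[[`, character(1), "id")
  segs
}

#' Beach segments of a scenario as a data frame
#'
#' @param scenario a [make_scenario()] result.
#' @return data frame with one row per beach segment, ordered west to east:
#'   `id`, `lon_mid`, `lat_mid`, `length_m`, `exposure_deg`.
#' @export
beaches_df <- function(scenario) {
  stopifnot(inherits(scenario, "domain_scenario"))
  do.call(rbind, lapply(scenario$beaches, function(s)
    data.frame(id = s$id, lon_mid = s$lon_mid, lat_mid = s$lat_mid,
               length_m = s$length_m, exposure_deg = s$exposure_deg,
               row.names = NULL)))
}

#' Reflect a scenario about the domain's zonal midline
#'
#' Returns the scenario with land mask and bathymetry mirrored in latitude and
#' beaches rederived from the mirrored mask.  Used together with meridionally
#' mirrored winds and swapped colony handedness to audit the mirror symmetry
#' of the drift model: the mirrored configuration must produce the mirrored
#' stranding pattern.
#'
#' @param scenario a [make_scenario()] result.
#' @return a `domain_scenario` on the same grid.
#' @export
mirror_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "domain_scenario"))
  ny <- scenario$grid$ny
  land <- scenario$land_mask[ny:1, , drop = FALSE]
  depth <- scenario$bathymetry[ny:1, , drop = FALSE]
  out <- scenario
  out$land_mask <- land
  out$bathymetry <- depth
  out$beaches <- derive_beaches(scenario$grid, land,
                                scenario$params$beach_max_cells)
  out$preset <- paste0(scenario$preset, "_mirrored")
  out
}

#' Bilinearly interpolated water depth at positions
#'
#' @param scenario a [make_scenario()] result.
#' @param lon,lat positions, decimal degrees.
#' @return depths in metres (0 on land; land cells pull interpolated values
#'   towards 0 near the coast, consistently with velocity interpolation).
#' @export
depth_at <- function(scenario, lon, lat) {
  g <- scenario$grid
  i <- findInterval(lon, g$lon); i <- pmin(pmax(i, 1L), g$nx - 1L)
  j <- findInterval(lat, g$lat); j <- pmin(pmax(j, 1L), g$ny - 1L)
  wx <- pmin(pmax((lon - g$lon[i]) / g$dlon, 0), 1)
  wy <- pmin(pmax((lat - g$lat[j]) / g$dlat, 0), 1)
  b <- scenario$bathymetry
  b[cbind(j, i)] * (1 - wx) * (1 - wy) +
    b[cbind(j, i + 1L)] * wx * (1 - wy) +
    b[cbind(j + 1L, i)] * (1 - wx) * wy +
    b[cbind(j + 1L, i + 1L)] * wx * wy
}
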