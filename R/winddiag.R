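# Wind diagnostics: monthly zonal-wind climatology over a box, winter anomaly
# ratios against that climatology, and daily bulk kinematic wind stress at a
# point.

#' Monthly climatology of the zonal wind over a box
#'
#' For every calendar month, the cos(latitude)-area-weighted mean of the
#' zonal component `u` over the box is computed per (year, month) and then
#' averaged across years — the standard long-term monthly climatology used to
#' put one winter's westerlies in context.
#'
#' @param winds a [vector_field()] of 10-m winds (time-resolved).
#' @param box `c(lon_min, lon_max, lat_min, lat_max)`; must intersect the
#'   grid.
#' @param years optional integer vector of calendar years to use; default all
#'   years present.
#' @return an object of class `zonal_wind_climatology`: list with `months`
#'   (abbreviated labels), `mean_u` (12 values, m/s, `NA` where no data),
#'   `years_used`, `box`, `n_samples` per month.
#' @export
monthly_zonal_climatology <- function(winds, box, years = NULL) {
  g <- winds$grid
  ii <- which(g$lon >= box[1] & g$lon <= box[2])
  jj <- which(g$lat >= box[3] & g$lat <= box[4])
  if (!length(ii) || !length(jj))
    stop("box lies outside the wind grid")
  times <- g$times
  yr <- as.integer(format(times, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  keep <- which(yr %in% years)
  if (!length(keep)) stop("no wind snapshots within the requested years")
  w <- rep(cos(g$lat[jj] * pi / 180), times = length(ii))
  wsum <- sum(w)
  nt_arr <- dim(winds$u)[3]
  ubar <- vapply(keep, function(k) {
    kk <- if (nt_arr == 1L) 1L else k
    sum(winds$u[jj, ii, kk] * w) / wsum
  }, numeric(1))
  mo <- as.integer(format(times[keep], "%m"))
  ykm <- paste(yr[keep], mo)
  per_ym <- tapply(ubar, ykm, mean)
  ym_month <- as.integer(sub("^\\d+ ", "", names(per_ym)))
  mean_u <- vapply(1:12, function(m) {
    v <- per_ym[ym_month == m]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  n_samples <- vapply(1:12, function(m) sum(mo == m), integer(1))
  structure(list(months = month.abb, mean_u = mean_u,
                 years_used = sort(unique(yr[keep])), box = box,
                 n_samples = n_samples),
            class = "zonal_wind_climatology")
}

#' @export
print.zonal_wind_climatology <- function(x, ...) {
  cat(sprintf("zonal_wind_climatology: years %d-%d, box [%.1f, %.1f] x [%.1f, %.1f]\n",
              min(x$years_used), max(x$years_used),
              x$box[1], x$box[2], x$box[3], x$box[4]))
  print(stats::setNames(round(x$mean_u, 2), x$months))
  invisible(x)
}

#' Ratio of one winter's monthly means to the climatology
#'
#' `ratio = target / climatology` per month.  Months where the climatological
#' mean is (numerically) zero, or where target and climatology have opposite
#' signs, are flagged undefined (`NA` ratio, `flag = TRUE`) rather than
#' returned as infinities or misleading negative factors — an anomaly
#' "x times stronger" only makes sense for same-direction winds.
#'
#' @param target named numeric vector of monthly means (names in
#'   `month.abb`), or a second `zonal_wind_climatology`.
#' @param clim a [monthly_zonal_climatology()] result.
#' @return data frame with `month`, `target`, `climatology`, `ratio`, `flag`.
#' @export
anomaly_ratio <- function(target, clim) {
  stopifnot(inherits(clim, "zonal_wind_climatology"))
  if (inherits(target, "zonal_wind_climatology"))
    target <- stats::setNames(target$mean_u, target$months)
  if (is.null(names(target)))
    stop("target must be named by month (month.abb)")
  m <- match(names(target), month.abb)
  if (anyNA(m)) stop("target names must be abbreviated months (month.abb)")
  cl <- clim$mean_u[m]
  bad <- abs(cl) < 1e-12 | (target != 0 & sign(target) * sign(cl) < 0)
  ratio <- ifelse(bad, NA_real_, target / cl)
  data.frame(month = names(target), target = as.numeric(target),
             climatology = cl, ratio = ratio, flag = bad,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Daily bulk kinematic wind stress at a point
#'
#' The standard bulk form `tau / rho = Cd * |w| * (w_x, w_y)` (units m^2/s^2)
#' evaluated at the wind samples interpolated to `(lon, lat)`, then averaged
#' per calendar day.
#'
#' @param winds a [vector_field()] of 10-m winds.
#' @param lon,lat the location; must lie on the grid.
#' @param Cd dimensionless drag coefficient; default `1.3e-3`.
#' @return an object of class `stress_series`: data frame with `date`,
#'   `tau_x`, `tau_y`, and `location`/`Cd` attributes.
#' @export
kinematic_wind_stress <- function(winds, lon, lat, Cd = 1.3e-3) {
  if (!(Cd > 0)) stop("Cd must be positive")
  g <- winds$grid
  if (lon < g$lon_min || lon > g$lon_max || lat < g$lat_min ||
      lat > g$lat_max)
    stop("location lies off the wind grid")
  times <- g$times
  uv <- vapply(seq_along(times), function(k) {
    s <- field_sample(winds, lon, lat, times[k])
    c(s$u, s$v)
  }, numeric(2))
  spd <- sqrt(uv[1, ]^2 + uv[2, ]^2)
  tx <- Cd * spd * uv[1, ]
  ty <- Cd * spd * uv[2, ]
  day <- as.Date(times, tz = "UTC")
  out <- data.frame(
    date = as.Date(levels(factor(day))),
    tau_x = as.numeric(tapply(tx, day, mean)),
    tau_y = as.numeric(tapply(ty, day, mean)),
    row.names = NULL
  )
  attr(out, "location") <- c(lon = lon, lat = lat)
  attr(out, "Cd") <- Cd
  class(out) <- c("stress_series", "data.frame")
  out
}
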