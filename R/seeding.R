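# Seeding virtual populations in a bathymetric depth band.

#' Seed a virtual population uniformly over a depth band
#'
#' Draws `n` colony positions uniformly over the area of the region whose
#' (bilinearly interpolated) water depth lies in `[depth_min, depth_max]` —
#' the reference configuration being 25,000 colonies between the 20 m coastal
#' isobath and the 200 m continental-slope isobath.  Sampling is rejection
#' sampling on the band's bounding box with a cos(latitude) latitude density,
#' so positions are uniform over area, and is bit-reproducible given
#' `rng_seed`.
#'
#' Handedness labels (`"none"`, `"left"`, `"right"`) are assigned in the exact
#' proportions of `handedness_mix` (largest-remainder rounding) and permuted
#' at random.  The main model run uses `c(none = 1)`; left/right mixes exist
#' for the handedness sensitivity experiment.
#'
#' @param scenario a [make_scenario()] result.
#' @param depth_min,depth_max band limits in metres, `0 < depth_min <
#'   depth_max`.
#' @param n number of colonies.
#' @param handedness_mix named fractions over `none`/`left`/`right`, summing
#'   to 1 (tolerance 1e-9).
#' @param rng_seed integer seed; the population is a pure function of
#'   (scenario, parameters, seed).
#' @param bbox optional `c(lon_min, lon_max, lat_min, lat_max)` restricting
#'   seeding to a sub-region of the band (e.g. one stretch of coast).
#' @return an object of class `drift_population`: a data frame with columns
#'   `id` (0-based, contiguous), `lon`, `lat`, `handedness`, `status`
#'   (all `"active"`), `strand_time`, `strand_segment`, plus `rng_seed` and
#'   `provenance` attributes sufficient to regenerate it.
#' @export
seed_depth_band <- function(scenario, depth_min, depth_max, n,
                            handedness_mix = c(none = 1), rng_seed = 1L,
                            bbox = NULL) {
  stopifnot(inherits(scenario, "domain_scenario"))
  if (!(depth_min > 0) || !(depth_max > depth_min))
    stop("need 0 < depth_min < depth_max")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1")
  hx <- handedness_mix
  if (is.null(names(hx)) || !all(names(hx) %in% c("none", "left", "right")))
    stop("handedness_mix must be named with 'none', 'left', 'right'")
  if (abs(sum(hx) - 1) > 1e-9)
    stop("handedness fractions must sum to 1 (tolerance 1e-9)")

  g <- scenario$grid
  sea <- !scenario$land_mask
  band <- sea & scenario$bathymetry >= depth_min &
    scenario$bathymetry <= depth_max
  if (!is.null(bbox)) {
    inlon <- g$lon >= bbox[1] & g$lon <= bbox[2]
    inlat <- g$lat >= bbox[3] & g$lat <= bbox[4]
    band <- band & outer(inlat, inlon)
  }
  if (!any(band)) stop("no ocean area within the requested depth band")
  jj <- row(band)[band]; ii <- col(band)[band]
  lon_lo <- min(g$lon[ii]) - g$dlon; lon_hi <- max(g$lon[ii]) + g$dlon
  lat_lo <- min(g$lat[jj]) - g$dlat; lat_hi <- max(g$lat[jj]) + g$dlat
  if (!is.null(bbox)) {
    lon_lo <- max(lon_lo, bbox[1]); lon_hi <- min(lon_hi, bbox[2])
    lat_lo <- max(lat_lo, bbox[3]); lat_hi <- min(lat_hi, bbox[4])
  }
  sin_lo <- sin(lat_lo * pi / 180); sin_hi <- sin(lat_hi * pi / 180)

  pos <- with_seed(rng_seed, {
    lon <- numeric(0); lat <- numeric(0)
    tries <- 0L
    while (length(lon) < n) {
      m <- max(1000L, 2L * (n - length(lon)))
      plon <- stats::runif(m, lon_lo, lon_hi)
      plat <- asin(stats::runif(m, sin_lo, sin_hi)) * 180 / pi
      d <- depth_at(scenario, plon, plat)
      wet <- on_land(scenario$land_mask, g, plon, plat)
      ok <- !is.na(wet) & !wet & d >= depth_min & d <= depth_max
      lon <- c(lon, plon[ok]); lat <- c(lat, plat[ok])
      tries <- tries + 1L
      if (tries > 1000L)
        stop("depth-band rejection sampling failed to converge")
    }
    hand <- assign_handedness(n, hx)
    list(lon = lon[seq_len(n)], lat = lat[seq_len(n)], hand = hand)
  })

  pop <- data.frame(
    id = 0:(n - 1L),
    lon = pos$lon, lat = pos$lat,
    handedness = pos$hand,
    status = rep("active", n),
    strand_time = as.POSIXct(rep(NA_real_, n), tz = "UTC",
                             origin = "1970-01-01"),
    strand_segment = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  attr(pop, "rng_seed") <- rng_seed
  attr(pop, "provenance") <- list(
    preset = scenario$preset, depth_min = depth_min, depth_max = depth_max,
    n = n, handedness_mix = as.list(hx), rng_seed = rng_seed,
    bbox = bbox
  )
  class(pop) <- c("drift_population", "data.frame")
  pop
}

# Exact largest-remainder allocation of handedness labels, then a random
# permutation (consumes RNG inside the caller's with_seed scope).
assign_handedness <- function(n, mix) {
  labels <- names(mix)
  exact <- mix * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(labels, times = base))
}

#' @export
print.drift_population <- function(x, ...) {
  cat(sprintf("drift_population: %d colonies (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$status),
                            names(table(x$status))), collapse = ", ")))
  hm <- table(x$handedness)
  cat("  handedness:", paste(sprintf("%s=%d", names(hm), hm), collapse = " "),
      "\n")
  invisible(x)
}
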