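# Small planar polygon utilities (local equirectangular metric).

# Signed area in degree coordinates (sign only; orientation test).
signed_area_deg <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Area of a lon/lat polygon in square metres
#'
#' Shoelace formula in the local equirectangular metric with cos(latitude)
#' scaling at the polygon's mean latitude.
#'
#' @param poly two-column matrix of (lon, lat) vertices, open or closed.
#' @return area in m^2.
#' @export
polygon_area_m2 <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) return(0)
  cphi <- cos(mean(poly[, 2]) * pi / 180)
  x <- poly[, 1] * M_PER_DEG * cphi
  y <- poly[, 2] * M_PER_DEG
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clipping of a polygon by a convex clip polygon.
# Both in (lon, lat); returns the intersection vertices or NULL if empty.
convex_clip <- function(subject, clip) {
  subject <- as.matrix(subject); clip <- as.matrix(clip)
  if (signed_area_deg(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[e, ]; b <- clip[e %% nc + 1L, ]
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) -
            (b[2] - a[2]) * (out[, 1] - a[1])
    nin <- nrow(out)
    res <- matrix(numeric(0), 0, 2)
    for (k in seq_len(nin)) {
      kp <- if (k == 1L) nin else k - 1L
      cur_in <- side[k] >= -1e-15
      prev_in <- side[kp] >= -1e-15
      if (cur_in != prev_in) {
        tt <- side[kp] / (side[kp] - side[k])
        res <- rbind(res, out[kp, ] + tt * (out[k, ] - out[kp, ]))
      }
      if (cur_in) res <- rbind(res, out[k, ])
    }
    out <- res
  }
  if (is.null(out) || nrow(out) < 3L) NULL else out
}

#' Jaccard overlap of two convex lon/lat polygons
#'
#' Intersection over union of areas, computed in the local equirectangular
#' metric.  Returns 0 for disjoint or degenerate polygons.
#'
#' @param poly1,poly2 two-column (lon, lat) vertex matrices; `poly2` must be
#'   convex.
#' @return Jaccard index in `[0, 1]`.
#' @export
hull_jaccard <- function(poly1, poly2) {
  a1 <- polygon_area_m2(poly1); a2 <- polygon_area_m2(poly2)
  if (a1 <= 0 || a2 <= 0) return(0)
  inter <- convex_clip(poly1, poly2)
  ai <- if (is.null(inter)) 0 else polygon_area_m2(inter)
  ai / (a1 + a2 - ai)
}

#' Axis-aligned bounding polygon of a point set
#'
#' @param lon,lat coordinate vectors.
#' @param pad optional padding in degrees.
#' @return a 4 x 2 (lon, lat) matrix (counterclockwise rectangle).
#' @export
bounding_polygon <- function(lon, lat, pad = 0) {
  cbind(lon = c(min(lon) - pad, max(lon) + pad, max(lon) + pad,
                min(lon) - pad),
        lat = c(min(lat) - pad, min(lat) - pad, max(lat) + pad,
                max(lat) + pad))
}
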