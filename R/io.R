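# Plain-text serialization: self-describing JSON for gridded fields, GeoJSON
# for beach segments, CSV (+ JSON provenance sidecar) for populations and
# stranding ledgers.

#' Write a gridded vector field to a self-describing JSON file
#'
#' The file records the coordinate vectors (`lon`, `lat`, `time` as ISO 8601
#' UTC), the array dimensions, the `u`/`v` components and the land mask, so
#' [read_vector_field()] reconstructs the field exactly.
#'
#' @param field a [vector_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  g <- field$grid
  payload <- list(
    conventions = "windrift-field-1",
    lon_min = g$lon_min, lon_max = g$lon_max,
    lat_min = g$lat_min, lat_max = g$lat_max,
    nx = g$nx, ny = g$ny,
    time = format(g$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    dims = dim(field$u),
    u = as.vector(field$u), v = as.vector(field$v),
    mask = as.vector(field$mask)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gridded vector field written by [write_vector_field()]
#'
#' @param path file path.
#' @return a [vector_field()].
#' @export
read_vector_field <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$conventions, "windrift-field-1"))
    stop("not a windrift field file")
  g <- grid_spec(p$lon_min, p$lon_max, p$lat_min, p$lat_max, p$nx, p$ny,
                 as.POSIXct(p$time, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ"))
  dims <- as.integer(p$dims)
  vector_field(g, array(p$u, dims), array(p$v, dims),
               matrix(as.logical(p$mask), p$ny, p$nx))
}

#' Write beach segments as GeoJSON LineString features
#'
#' @param scenario a [make_scenario()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beaches_geojson <- function(scenario, path) {
  feats <- lapply(scenario$beaches, function(s) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(s$vertices)),
                           function(k) as.numeric(s$vertices[k, ]))),
         properties = list(id = s$id, length_m = s$length_m,
                           exposure_deg = s$exposure_deg))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(feats)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read beach segments from a GeoJSON file
#'
#' @param path a file written by [write_beaches_geojson()] (or any GeoJSON
#'   FeatureCollection of LineStrings with `id`, `length_m`, `exposure_deg`
#'   properties).
#' @return a list of beach segments keyed by id.
#' @export
read_beaches_geojson <- function(path) {
  p <- jsonlite::read_json(path)
  segs <- lapply(p$features, function(f) {
    verts <- do.call(rbind, lapply(f$geometry$coordinates, as.numeric))
    colnames(verts) <- c("lon", "lat")
    list(id = f$properties$id, vertices = verts,
         length_m = f$properties$length_m,
         exposure_deg = f$properties$exposure_deg,
         lon_mid = mean(verts[, 1]), lat_mid = mean(verts[, 2]))
  })
  names(segs) <- vapply(segs, `[[`, character(1), "id")
  segs
}

#' Write a population to CSV with a JSON provenance sidecar
#'
#' @param pop a [seed_depth_band()] population.
#' @param path CSV output path; provenance goes to `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop)[, c("id", "lon", "lat", "handedness",
                                          "status")],
                   path, row.names = FALSE)
  prov <- attr(pop, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a population CSV written by [write_population()]
#'
#' @param path CSV path.
#' @return a `drift_population` data frame (provenance reattached when the
#'   sidecar file exists).
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$strand_time <- as.POSIXct(rep(NA_real_, nrow(df)), tz = "UTC",
                               origin = "1970-01-01")
  df$strand_segment <- NA_character_
  side <- paste0(path, ".provenance.json")
  if (file.exists(side))
    attr(df, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  class(df) <- c("drift_population", "data.frame")
  df
}

#' Write a stranding ledger to CSV
#'
#' @param strandings the `strandings` data frame of a [run_simulation()]
#'   result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_strandings <- function(strandings, path) {
  out <- strandings
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a stranding ledger CSV
#'
#' @param path CSV path.
#' @return data frame with `particle_id`, `time` (POSIXct), `lon`, `lat`,
#'   `segment_id`.
#' @export
read_strandings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time <- as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  df
}
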