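# Aggregating stranding events per beach and comparing stranding patterns.

#' Assign stranding records to beach segments
#'
#' Each record is assigned to the beach segment at minimal distance from its
#' coordinates (local equirectangular metric, consistent with the package's
#' geometry conventions); ties break to the lower segment id.  Records
#' farther than `max_cells` grid cells from every segment are flagged
#' unassigned (`NA`) but kept.
#'
#' @param records data frame with `lon` and `lat` columns (e.g. the
#'   `strandings` element of a [run_simulation()] result).
#' @param scenario a [make_scenario()] result.
#' @param max_cells assignment radius in grid cells; default 2.
#' @return character vector of segment ids (`NA` where unassigned).
#' @export
assign_to_beach <- function(records, scenario, max_cells = 2) {
  stopifnot(inherits(scenario, "domain_scenario"))
  lon <- records$lon; lat <- records$lat
  n <- length(lon)
  if (!n) return(character(0))
  beaches <- scenario$beaches
  dm <- matrix(Inf, n, length(beaches))
  cphi <- cos(lat * pi / 180)
  for (b in seq_along(beaches)) {
    v <- beaches[[b]]$vertices
    dbest <- rep(Inf, n)
    for (s in seq_len(nrow(v) - 1L)) {
      x <- (lon - v[s, 1]) * M_PER_DEG * cphi
      y <- (lat - v[s, 2]) * M_PER_DEG
      dx <- (v[s + 1L, 1] - v[s, 1]) * M_PER_DEG * cphi
      dy <- (v[s + 1L, 2] - v[s, 2]) * M_PER_DEG
      tt <- pmin(1, pmax(0, (x * dx + y * dy) / pmax(dx^2 + dy^2, 1e-12)))
      dbest <- pmin(dbest, sqrt((x - tt * dx)^2 + (y - tt * dy)^2))
    }
    dm[, b] <- dbest
  }
  best <- max.col(-dm, ties.method = "first")   # lowest id wins ties
  dmin <- dm[cbind(seq_len(n), best)]
  thr <- max_cells * max(cell_size_m(scenario$grid))
  ids <- unname(vapply(beaches, `[[`, character(1), "id"))
  out <- ids[best]
  out[dmin > thr] <- NA_character_
  out
}

#' Count strandings and first arrivals per beach
#'
#' @param records stranding records (`segment_id`, `time`) as produced by
#'   [run_simulation()].
#' @param scenario a [make_scenario()] result.
#' @return data frame with one row per beach (west to east): `beach_id`,
#'   `count`, `first_arrival` (NA where no arrivals), plus an `unassigned`
#'   attribute with the number of records without a segment.
#' @export
count_strandings <- function(records, scenario) {
  ids <- vapply(scenario$beaches, `[[`, character(1), "id")
  seg <- records$segment_id
  cnt <- table(factor(seg, levels = ids))
  first <- rep(as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01"),
               length(ids))
  if (nrow(records)) {
    for (k in seq_along(ids)) {
      tt <- records$time[!is.na(seg) & seg == ids[k]]
      if (length(tt)) first[k] <- min(tt)
    }
  }
  out <- data.frame(beach_id = ids, count = as.integer(cnt),
                    first_arrival = first, stringsAsFactors = FALSE)
  attr(out, "unassigned") <- sum(is.na(seg))
  out
}

#' Stranding densities per 100 m of coastline
#'
#' Converts per-beach counts into cumulative densities
#' `100 * count / length_m`, the unit in which observed and simulated beaching
#' patterns are compared.  Beaches without strandings are kept with density 0;
#' the table is ordered west to east.
#'
#' @param counts data frame with `beach_id` and `count` (and optionally
#'   `first_arrival`), or a named count vector.
#' @param scenario a [make_scenario()] result supplying segment lengths, or a
#'   data frame with `beach_id`, `length_m` (and optionally `lon_mid`).
#' @return an object of class `stranding_density_table`: data frame with
#'   `beach_id`, `lon_mid`, `length_m`, `count`, `density_per_100m`,
#'   `first_arrival`.
#' @export
density_per_100m <- function(counts, scenario) {
  if (!is.data.frame(counts))
    counts <- data.frame(beach_id = names(counts),
                         count = as.numeric(counts),
                         stringsAsFactors = FALSE)
  if (any(counts$count < 0)) stop("stranding counts must be non-negative")
  beaches <- if (inherits(scenario, "domain_scenario")) {
    bd <- beaches_df(scenario)
    data.frame(beach_id = bd$id, lon_mid = bd$lon_mid,
               length_m = bd$length_m, stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("beach_id", "length_m") %in% names(scenario)))
    data.frame(beach_id = scenario$beach_id,
               lon_mid = if ("lon_mid" %in% names(scenario))
                 scenario$lon_mid else seq_along(scenario$beach_id),
               length_m = scenario$length_m, stringsAsFactors = FALSE)
  }
  unknown <- setdiff(counts$beach_id, c(beaches$beach_id, NA))
  if (length(unknown))
    stop(sprintf("counted beaches not in the scenario: %s",
                 paste(unknown, collapse = ", ")))
  m <- match(beaches$beach_id, counts$beach_id)
  cnt <- ifelse(is.na(m), 0, counts$count[m])
  fa <- rep(as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01"),
            nrow(beaches))
  if ("first_arrival" %in% names(counts))
    fa[!is.na(m)] <- counts$first_arrival[m[!is.na(m)]]
  out <- data.frame(beach_id = beaches$beach_id, lon_mid = beaches$lon_mid,
                    length_m = beaches$length_m, count = cnt,
                    density_per_100m = 100 * cnt / beaches$length_m,
                    first_arrival = fa, stringsAsFactors = FALSE)
  out <- out[order(out$lon_mid, out$beach_id), ]
  rownames(out) <- NULL
  class(out) <- c("stranding_density_table", "data.frame")
  out
}

#' Compare simulated and observed stranding patterns
#'
#' The headline comparison is rank-based: a Spearman correlation of per-beach
#' densities over the outer-joined beach set (missing beaches counted as 0),
#' because the claim under test is similarity of the spatial pattern, not of
#' magnitudes.  Magnitude agreement is reported as the RMS difference of log
#' densities over beaches that are nonzero in both tables, and west-to-east
#' arrival ordering as the Spearman correlation between beach longitude rank
#' and first-arrival time rank within each table.
#'
#' @param sim,obs [density_per_100m()] tables.
#' @return an object of class `pattern_comparison`: list with
#'   `spearman_density`, `rms_log_density`, `arrival_concordance`
#'   (`sim`/`obs`), `n_beaches`, and the joined `table`.
#' @export
compare_patterns <- function(sim, obs) {
  ids <- union(sim$beach_id, obs$beach_id)
  if (length(ids) < 3L)
    stop("fewer than 3 shared beaches: rank correlation undefined")
  ms <- match(ids, sim$beach_id); mo <- match(ids, obs$beach_id)
  ds <- ifelse(is.na(ms), 0, sim$density_per_100m[ms])
  do <- ifelse(is.na(mo), 0, obs$density_per_100m[mo])
  lon <- ifelse(!is.na(ms), sim$lon_mid[ms], obs$lon_mid[mo])
  rho <- stats::cor(ds, do, method = "spearman")
  both <- ds > 0 & do > 0
  rms <- if (any(both)) sqrt(mean((log(ds[both]) - log(do[both]))^2))
         else NA_real_
  concord <- function(tab) {
    if (!"first_arrival" %in% names(tab)) return(NA_real_)
    ok <- !is.na(tab$first_arrival)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(rank(tab$lon_mid[ok]),
               rank(as.numeric(tab$first_arrival[ok])),
               method = "spearman")
  }
  joined <- data.frame(beach_id = ids, lon_mid = lon, sim_density = ds,
                       obs_density = do, stringsAsFactors = FALSE)
  structure(list(
    spearman_density = rho,
    rms_log_density = rms,
    arrival_concordance = list(sim = concord(sim), obs = concord(obs)),
    n_beaches = length(ids),
    table = joined[order(joined$lon_mid), ]
  ), class = "pattern_comparison")
}

#' @export
print.pattern_comparison <- function(x, ...) {
  cat("pattern_comparison over", x$n_beaches, "beaches\n")
  cat(sprintf("  Spearman rho (densities):          %.3f\n",
              x$spearman_density))
  cat(sprintf("  RMS log-density difference:        %s\n",
              if (is.na(x$rms_log_density)) "NA"
              else sprintf("%.3f", x$rms_log_density)))
  cat(sprintf("  west-to-east arrival concordance:  sim %s, obs %s\n",
              format(x$arrival_concordance$sim, digits = 3),
              format(x$arrival_concordance$obs, digits = 3)))
  invisible(x)
}

#' Read an observed stranding ledger
#'
#' Expects a CSV with header `beach_id,date,count,mean_size_cm`
#' (`mean_size_cm` may be empty).
#'
#' @param path CSV file path.
#' @return data frame of class `observed_strandings`.
#' @export
read_observed_strandings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("beach_id", "date", "count")
  if (!all(need %in% names(df)))
    stop("observed strandings need columns beach_id, date, count")
  if (any(df$count < 0)) stop("observed counts must be non-negative")
  df$date <- as.POSIXct(df$date, tz = "UTC")
  if (!"mean_size_cm" %in% names(df)) df$mean_size_cm <- NA_real_
  class(df) <- c("observed_strandings", "data.frame")
  df
}

#' Aggregate an observed ledger into a density table
#'
#' Counts are summed per beach over the (optional) analysis window —
#' "cumulative density" — and the first sampled date per beach stands in for
#' the first-arrival time.
#'
#' @param obs an [read_observed_strandings()] data frame.
#' @param beaches a scenario or a `beach_id`/`length_m` data frame (see
#'   [density_per_100m()]).
#' @param window optional length-2 timestamps restricting the dates used.
#' @return a [density_per_100m()] table.
#' @export
observed_density <- function(obs, beaches, window = NULL) {
  if (!is.null(window)) {
    w <- as.POSIXct(window, tz = "UTC")
    obs <- obs[obs$date >= w[1] & obs$date <= w[2], , drop = FALSE]
  }
  agg <- stats::aggregate(count ~ beach_id, data = obs, FUN = sum)
  fa <- stats::aggregate(date ~ beach_id, data = obs, FUN = min)
  agg$first_arrival <- fa$date[match(agg$beach_id, fa$beach_id)]
  density_per_100m(agg, beaches)
}
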