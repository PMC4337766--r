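#' Great-circle distance on a spherical Earth
#'
#' Haversine distance between pairs of coordinates on a sphere of radius
#' 6371 km. The haversine form is numerically stable for the short
#' (sub-kilometre to few-kilometre) hourly steps typical of GPS telemetry.
#'
#' @param lat1,lon1 Origin coordinates in decimal degrees.
#' @param lat2,lon2 Destination coordinates in decimal degrees.
#' @param radius_km Sphere radius in kilometres.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' gc_dist_km(0, 37, 0, 38) # one degree of longitude on the equator
#' @export
gc_dist_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  if (!all(is.finite(lat1), is.finite(lon1), is.finite(lat2), is.finite(lon2))) {
    stop("coordinates must be finite")
  }
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90)) {
    stop("latitudes must lie in [-90, 90]")
  }
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Regularize a GPS track onto an hourly grid and interpolate failed fixes
#'
#' Builds the complete hourly grid between the first and last successful fix
#' of each individual and fills failed (or absent) hourly slots by linear
#' interpolation of latitude and longitude, independently and in raw
#' degrees, between the temporally nearest successful fixes. Interpolation
#' in degrees rather than along the great circle is an approximation that
#' is excellent at hourly step sizes. Slots before the first or after the
#' last successful fix cannot be interpolated and are dropped; any days
#' they would belong to are consequently incomplete and invalid downstream.
#'
#' @param tracks Data frame with columns `individual_id`, `timestamp`
#'   (POSIXct, on an hourly grid), `lat`, `lon`, `success` (logical or 0/1).
#'   Rows missing from the grid are treated as failed fixes.
#' @return A tibble with one row per hourly slot per individual and columns
#'   `individual_id`, `timestamp`, `lat`, `lon`, `success`, `interpolated`.
#' @export
regularize_tracks <- function(tracks) {
  stopifnot(all(c("individual_id", "timestamp", "lat", "lon", "success") %in%
                  names(tracks)))
  if (!inherits(tracks$timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct")
  }
  out <- lapply(split(tracks, tracks$individual_id), regularize_one)
  dplyr::bind_rows(out)
}

regularize_one <- function(track) {
  track <- track[order(track$timestamp), ]
  ok <- as.logical(track$success) & is.finite(track$lat) & is.finite(track$lon)
  succ <- track[ok, ]
  if (nrow(succ) < 2) {
    stop("need at least two successful fixes per individual")
  }
  t0 <- as.numeric(succ$timestamp[1])
  t1 <- as.numeric(succ$timestamp[nrow(succ)])
  ts <- as.numeric(succ$timestamp)
  if (anyDuplicated(ts) || any((ts - t0) %% 3600 != 0)) {
    stop("timestamps must be unique and lie on a common hourly grid")
  }
  grid <- seq(t0, t1, by = 3600)
  lat <- stats::approx(ts, succ$lat, xout = grid)$y
  lon <- stats::approx(ts, succ$lon, xout = grid)$y
  success <- grid %in% ts
  tibble::tibble(
    individual_id = track$individual_id[1],
    timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    lat = lat, lon = lon,
    success = success,
    interpolated = !success
  )
}

local_day <- function(timestamp, day_offset_hours) {
  h <- as.numeric(timestamp) %/% 3600 + day_offset_hours
  as.Date(h %/% 24, origin = "1970-01-01")
}

#' Hourly net displacements from a regularized track
#'
#' The hourly net displacement series is the great-circle distance between
#' successive hourly positions. The displacement for hour *t* spans
#' positions at *t* and *t*+1 and is assigned to the day containing *t*, so
#' each complete day owns exactly 24 hourly displacements (the last of
#' which reaches into the following day's first fix). Days are bounded at
#' local midnight, offset from UTC by `day_offset_hours`.
#'
#' @param reg Output of [regularize_tracks()].
#' @param day_offset_hours Hours ahead of UTC of the local day boundary
#'   (default 3, East Africa Time).
#' @return A tibble with columns `individual_id`, `timestamp`, `date`
#'   (local day), `disp_km`, `interpolated` (either endpoint interpolated)
#'   and `fix_success` (success of the fix opening the hour).
#' @export
hourly_displacements <- function(reg, day_offset_hours = 3) {
  out <- lapply(split(reg, reg$individual_id), function(g) {
    g <- g[order(g$timestamp), ]
    n <- nrow(g)
    if (n < 2) stop("regularized track has fewer than two fixes")
    tibble::tibble(
      individual_id = g$individual_id[1],
      timestamp = g$timestamp[-n],
      date = local_day(g$timestamp[-n], day_offset_hours),
      disp_km = gc_dist_km(g$lat[-n], g$lon[-n], g$lat[-1], g$lon[-1]),
      interpolated = g$interpolated[-n] | g$interpolated[-1],
      fix_success = g$success[-n]
    )
  })
  dplyr::bind_rows(out)
}

#' Diel displacement per individual-day
#'
#' Sums the 24 hourly displacements of each local day (interpolated hours
#' included) into the diel displacement DD. A day is valid when at least 20
#' of its 24 hourly fixes succeeded and all 24 hourly displacements exist;
#' partial days at the edges of a track get `dd_km = NA`. Invalid days are
#' retained (flagged) so completeness can be audited, but are excluded from
#' modelling downstream.
#'
#' @param disp Output of [hourly_displacements()].
#' @param min_fixes Minimum successful fixes for a valid day (default 20).
#' @return A tibble with columns `individual_id`, `date`, `dd_km`,
#'   `n_fixes`, `valid`.
#' @export
diel_displacement <- function(disp, min_fixes = 20) {
  agg <- dplyr::summarise(
    dplyr::group_by(disp, .data$individual_id, .data$date),
    dd_km = sum(.data$disp_km),
    n_disp = dplyr::n(),
    n_fixes = sum(.data$fix_success),
    .groups = "drop"
  )
  agg$dd_km[agg$n_disp < 24] <- NA_real_
  agg$valid <- agg$n_disp == 24 & agg$n_fixes >= min_fixes
  agg$n_disp <- NULL
  agg
}

#' Model rows with two lagged responses
#'
#' Extracts one row per day *i* such that days *i*, *i*-1 and *i*-2 are all
#' valid, consecutive calendar days for that individual; the lag fields
#' carry the response observed on the two preceding days. These triplets
#' are the data to which the mixed models are fit.
#'
#' @param records Diel records ([diel_displacement()] output, optionally
#'   augmented with `mp`, `ndvi`, `forage_category`, `rank` columns).
#' @param response `"dd"` (uses `dd_km`) or `"mp"` (uses `mp`).
#' @return A tibble with columns `individual_id`, `date`, `y`, `lag1`,
#'   `lag2` plus any of `ndvi`, `forage_category`, `rank` present in
#'   `records`. May be empty.
#' @export
model_rows <- function(records, response = c("dd", "mp")) {
  response <- match.arg(response)
  col <- if (response == "dd") "dd_km" else "mp"
  if (!col %in% names(records)) {
    stop("records lack the '", col, "' column")
  }
  carry <- intersect(c("ndvi", "forage_category", "rank"), names(records))
  out <- lapply(split(records, records$individual_id), function(g) {
    g <- g[order(g$date), ]
    usable <- g$valid & !is.na(g[[col]])
    d <- as.numeric(g$date)
    i1 <- match(d - 1, d)
    i2 <- match(d - 2, d)
    # NA indices (no such calendar day) propagate NA and are dropped by which()
    keep <- which(usable & usable[i1] & usable[i2])
    if (!length(keep)) return(NULL)
    row <- tibble::tibble(
      individual_id = g$individual_id[keep],
      date = g$date[keep],
      y = g[[col]][keep],
      lag1 = g[[col]][i1[keep]],
      lag2 = g[[col]][i2[keep]]
    )
    for (cc in carry) row[[cc]] <- g[[cc]][keep]
    row
  })
  dplyr::bind_rows(out)
}
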