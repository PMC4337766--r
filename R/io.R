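#' Read tabular inputs
#'
#' CSV readers for the three input tables: hourly GPS tracks
#' (`individual_id,timestamp,lat,lon,success`, ISO-8601 UTC timestamps,
#' success coded 0/1), the daily NDVI series (`date,ndvi`) and the rank
#' table (`individual_id,rank`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "timestamp", "lat", "lon", "success")
                %in% names(d)))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC")
  d$success <- as.logical(as.integer(d$success))
  tibble::as_tibble(d)
}

#' @rdname read_tracks
#' @export
read_ndvi <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "ndvi") %in% names(d)))
  d$date <- as.Date(d$date)
  tibble::as_tibble(d)
}

#' @rdname read_tracks
#' @export
read_ranks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "rank") %in% names(d)))
  tibble::as_tibble(d)
}

#' Write diel records to CSV
#'
#' @param records Diel records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diel_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
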