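#' Attach daily NDVI values to diel records
#'
#' Looks up (or, for series coarser than daily, linearly interpolates in
#' time) the ecosystem NDVI value for each record's date. Records dated
#' outside the NDVI series span cannot be assigned and are dropped with a
#' warning.
#'
#' @param records Diel records (one row per individual-day).
#' @param ndvi Data frame with columns `date` and `ndvi`, dates increasing.
#' @return `records` with an `ndvi` column, minus out-of-span rows.
#' @export
assign_ndvi <- function(records, ndvi) {
  stopifnot(all(c("date", "ndvi") %in% names(ndvi)))
  if (!all(is.finite(ndvi$ndvi))) stop("NDVI values must be finite")
  if (is.unsorted(ndvi$date, strictly = TRUE)) stop("NDVI dates must increase")
  records$ndvi <- stats::approx(as.numeric(ndvi$date), ndvi$ndvi,
                                xout = as.numeric(records$date),
                                rule = 1)$y
  drop <- is.na(records$ndvi)
  if (any(drop)) {
    warning(sum(drop), " record(s) outside the NDVI series span were dropped")
    records <- records[!drop, ]
  }
  records
}

#' Equal-width NDVI bin edges
#'
#' The two interior cut points splitting the observed NDVI range into
#' three equal-width forage-availability intervals.
#'
#' @param x Observed NDVI values.
#' @return Numeric vector `c(e1, e2)`.
#' @export
forage_bins <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) stop("degenerate NDVI range: all values equal")
  r[1] + diff(r) * c(1, 2) / 3
}

#' Assign forage-availability categories
#'
#' Classifies each day as low (LFA), medium (MFA) or high (HFA) forage
#' availability using three equal-width bins over the NDVI range observed
#' across all *valid* movement days, pooled over individuals. Intervals
#' are half-open with a closed top (`[min, e1)`, `[e1, e2)`, `[e2, max]`)
#' so the partition is exhaustive.
#'
#' @param records Records with `ndvi` and `valid` columns.
#' @param edges Optional interior cut points; defaults to [forage_bins()]
#'   of the valid records' NDVI.
#' @return `records` with a `forage_category` factor column (levels LFA,
#'   MFA, HFA); the edges used are attached as attribute `bin_edges`.
#' @export
bin_forage <- function(records, edges = NULL) {
  if (!"ndvi" %in% names(records)) stop("assign_ndvi() first")
  if (is.null(edges)) {
    pool <- records$ndvi[records$valid]
    if (!length(pool)) stop("no valid records to compute bin edges from")
    edges <- forage_bins(pool)
  }
  cat3 <- ifelse(records$ndvi < edges[1], "LFA",
                 ifelse(records$ndvi < edges[2], "MFA", "HFA"))
  records$forage_category <- factor(cat3, levels = c("LFA", "MFA", "HFA"))
  attr(records, "bin_edges") <- edges
  records
}

#' Attach social rank to records
#'
#' @param records Diel records.
#' @param ranks Data frame with columns `individual_id` and `rank` (one of
#'   low, medium, variable, high).
#' @return `records` with a `rank` factor column (reference level "low").
#' @export
assign_rank <- function(records, ranks) {
  stopifnot(all(c("individual_id", "rank") %in% names(ranks)))
  ranks$rank <- factor(as.character(ranks$rank), levels = rank_levels())
  if (anyNA(ranks$rank)) stop("ranks must be one of: ",
                              paste(rank_levels(), collapse = ", "))
  records$rank <- NULL
  dplyr::left_join(records, ranks[, c("individual_id", "rank")],
                   by = "individual_id")
}

#' Ordered social-rank levels (reference first)
#' @return Character vector.
#' @export
rank_levels <- function() c("low", "medium", "variable", "high")
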