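#' Local linear (loess) trend
#'
#' Local regression with tricube weights over the span-nearest neighbours,
#' degree-1 (locally linear), evaluated on a grid. Uses the exact direct
#' surface so that exactly linear data are recovered exactly.
#'
#' @param x,y Numeric vectors (at least 10 points).
#' @param span Smoothing span in (0, 1].
#' @param degree Local polynomial degree (default 1).
#' @param grid Evaluation grid; defaults to 100 points over `range(x)`.
#' @return A tibble with columns `x` and `fitted`.
#' @export
loess_trend <- function(x, y, span = 0.75, degree = 1, grid = NULL) {
  if (length(x) < 10) stop("need at least 10 points")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (ceiling(span * length(x)) < degree + 2) {
    stop("span too small for the requested degree")
  }
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  tibble::tibble(x = grid, fitted = as.numeric(stats::predict(fit, grid)))
}

#' Mean and coefficient-of-variation trends of DD against NDVI
#'
#' The mean trend is a degree-1 loess of diel displacement on NDVI. The CV
#' trend is built from a sliding window along the NDVI axis (width = the
#' span-fraction of the data, i.e. the same neighbourhood size the loess
#' uses): within each window the SD/mean ratio is computed, and the
#' resulting points are loess-smoothed. Windows with mean zero are
#' skipped.
#'
#' @param records Valid diel records with `dd_km` and `ndvi`.
#' @param span Loess / window span.
#' @param grid NDVI evaluation grid (default 100 points over the range).
#' @return An object of class `loess_curve`: tibble with columns `ndvi`,
#'   `mean_dd`, `cv_dd`, with `span` and `degree` attributes.
#' @export
cv_trend <- function(records, span = 0.75, grid = NULL) {
  d <- records[records$valid & !is.na(records$dd_km) & !is.na(records$ndvi), ]
  n <- nrow(d)
  if (n < 10) stop("need at least 10 valid records")
  ord <- order(d$ndvi)
  x <- d$ndvi[ord]
  y <- d$dd_km[ord]
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)
  k <- max(4, ceiling(span * n))
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  centers <- (half + 1):(n - half)
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y^2))
  wmean <- (cs[centers + half + 1] - cs[centers - half]) / k
  wvar <- (cs2[centers + half + 1] - cs2[centers - half]) / k - wmean^2
  wsd <- sqrt(pmax(wvar * k / (k - 1), 0))
  keep <- wmean != 0
  cv <- wsd[keep] / wmean[keep]
  mean_curve <- loess_trend(x, y, span = span, grid = grid)
  cv_curve <- loess_trend(x[centers][keep], cv, span = span, grid = grid)
  out <- tibble::tibble(ndvi = grid, mean_dd = mean_curve$fitted,
                        cv_dd = cv_curve$fitted)
  attr(out, "span") <- span
  attr(out, "degree") <- 1
  class(out) <- c("loess_curve", class(out))
  out
}

#' Per-individual and pooled summaries by forage category
#'
#' Per individual and forage category: the median diel displacement (the
#' median damps the influence of occasional long-distance excursions), the
#' mean daily MP, and the day count. Pooled values are unweighted averages
#' of the per-individual statistics, so each individual contributes
#' equally regardless of tracking duration. The overall 0.95 quantile of
#' DD across all valid days is reported alongside.
#'
#' @param records Diel records with `forage_category` (and optionally
#'   `mp`).
#' @return A list with `individual` (tibble), `pooled` (tibble) and
#'   `dd_q95` (scalar).
#' @export
category_summaries <- function(records) {
  d <- records[records$valid & !is.na(records$forage_category), ]
  if (!"mp" %in% names(d)) d$mp <- NA_real_
  ind <- dplyr::summarise(
    dplyr::group_by(d, .data$individual_id, .data$forage_category),
    median_dd = stats::median(.data$dd_km, na.rm = TRUE),
    mean_mp = mean(.data$mp, na.rm = TRUE),
    n_days = dplyr::n(),
    .groups = "drop"
  )
  ind$mean_mp[is.nan(ind$mean_mp)] <- NA_real_
  pooled <- dplyr::summarise(
    dplyr::group_by(ind, .data$forage_category),
    median_dd = mean(.data$median_dd, na.rm = TRUE),
    mean_mp = mean(.data$mean_mp, na.rm = TRUE),
    n_days = sum(.data$n_days),
    n_individuals = dplyr::n(),
    .groups = "drop"
  )
  pooled$mean_mp[is.nan(pooled$mean_mp)] <- NA_real_
  list(individual = ind, pooled = pooled,
       dd_q95 = stats::quantile(d$dd_km, 0.95, na.rm = TRUE, names = FALSE))
}
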