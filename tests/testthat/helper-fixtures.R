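# Shared fixture builders. All synthetic, generated in code.

# POSIXct of local midnight (UTC+offset day boundary) for a given date
day_start <- function(date, day_offset_hours = 3) {
  as.POSIXct(as.numeric(as.Date(date)) * 86400 - day_offset_hours * 3600,
             origin = "1970-01-01", tz = "UTC")
}

# an hourly track from coordinate vectors, starting at local midnight
make_track <- function(lat, lon, success = TRUE, id = "A",
                       start = day_start("2001-01-01")) {
  n <- length(lat)
  tibble::tibble(
    individual_id = id,
    timestamp = start + 3600 * (seq_len(n) - 1),
    lat = lat, lon = lon,
    success = rep_len(success, n)
  )
}

# hourly displacement table straight from values (one individual),
# bypassing track geometry; days are complete by construction
make_disp <- function(values, id = "A", start_date = as.Date("2001-01-01"),
                      fix_success = TRUE) {
  stopifnot(length(values) %% 24 == 0)
  n <- length(values)
  tibble::tibble(
    individual_id = id,
    timestamp = day_start(start_date) + 3600 * (seq_len(n) - 1),
    date = rep(start_date + seq_len(n / 24) - 1, each = 24),
    disp_km = values,
    interpolated = FALSE,
    fix_success = rep_len(fix_success, n)
  )
}

# diel records table from a validity pattern
make_records <- function(valid, dd = NULL, id = "A",
                         start_date = as.Date("2001-01-01")) {
  n <- length(valid)
  tibble::tibble(
    individual_id = id,
    date = start_date + seq_len(n) - 1,
    dd_km = if (is.null(dd)) as.numeric(seq_len(n)) else dd,
    n_fixes = ifelse(valid, 24L, 10L),
    valid = valid
  )
}

# independent time-domain Morlet convolution oracle (quadratic cost)
cwt_direct_oracle <- function(x, periods, dt = 1, omega0 = 6) {
  n <- length(x)
  x0 <- x - mean(x)
  scales <- periods * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  P <- matrix(0, n, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    for (t in seq_len(n)) {
      eta <- ((seq_len(n)) - t) * dt / s
      w <- sqrt(dt / s) * pi^(-1 / 4) * exp(1i * omega0 * eta - eta^2 / 2)
      P[t, j] <- abs(sum(x0 * Conj(w)))^2
    }
  }
  P
}

table_dd_coef_named <- function() {
  c(ndvi = 0.38, `ndvi:rankmedium` = -0.05, `ndvi:rankvariable` = 0.02,
    `ndvi:rankhigh` = 0.23)
}

table_mp_coef_named <- function() {
  c(ndvi = 2.85, `ndvi:rankmedium` = -0.78, `ndvi:rankvariable` = -0.54,
    `ndvi:rankhigh` = -1.48)
}
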