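#' Per-day min-max normalization of hourly displacements
#'
#' Rescales the hourly net-displacement series to lie in \[0, 1\] within
#' each complete (24-hour) day separately, so that the spectral analysis
#' detects changes in periodicity rather than changes in variance. A
#' constant day maps to all zeros; incomplete edge days get `NA`.
#'
#' @param disp Output of [hourly_displacements()].
#' @return `disp` with an added `norm` column.
#' @export
normalize_daily <- function(disp) {
  key <- factor(paste(disp$individual_id, disp$date))
  norm_one <- function(v) {
    if (length(v) != 24 || anyNA(v)) return(rep(NA_real_, length(v)))
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  disp$norm <- unsplit(lapply(split(disp$disp_km, key), norm_one), key)
  disp
}

#' Normalized Fourier spectrum of an hourly series
#'
#' Mean-removed periodogram with a Tukey (cosine-bell) taper and a modified
#' Daniell smoother over immediately adjacent frequencies, normalized by
#' the series variance so that white noise has expected power 1 at every
#' frequency. Frequencies are reported in cycles/day for an hourly series.
#'
#' @param x Numeric series (hourly), length at least 48.
#' @param taper_fraction Proportion of the series tapered at each end.
#' @param smoother_spans Spans of the modified Daniell smoother.
#' @return A tibble with columns `freq_cpd` and `power`.
#' @export
fourier_spectrum <- function(x, taper_fraction = 0.1, smoother_spans = c(3, 3)) {
  if (length(x) < 48) stop("series must contain at least 48 hourly values")
  v <- stats::var(x)
  if (v == 0) stop("series is constant")
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1),
                          spans = smoother_spans, taper = taper_fraction,
                          demean = TRUE, detrend = FALSE,
                          plot = FALSE, fast = TRUE)
  tibble::tibble(freq_cpd = sp$freq * 24, power = sp$spec / v)
}

# Fourier factor of the Morlet wavelet: period = fourier_factor(omega0) * scale
fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# Frequency-domain Morlet daughters on the padded FFT grid, one column per scale.
morlet_daughters <- function(np, dt, scales, omega0) {
  k <- 2 * pi * c(0:(np %/% 2), -((np %/% 2 - 1):1)) / (np * dt)
  pos <- k > 0
  vapply(scales, function(s) {
    psi <- numeric(np)
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * k[pos] - omega0)^2 / 2)
    psi
  }, numeric(np))
}

#' Morlet continuous wavelet power spectrum
#'
#' Computes \eqn{|W(t, s)|^2} of a series by FFT convolution with the
#' analytic Morlet wavelet (centre frequency `omega0 = 6`, the standard
#' choice in movement and circadian ecology). The series is mean-removed
#' and zero-padded to at least twice the next power of two, which makes the
#' circular convolution equivalent to a time-domain convolution with zero
#' extension. Scales are parameterized by their equivalent Fourier period
#' in hours.
#'
#' @param x Numeric series on a regular hourly grid.
#' @param periods Fourier periods (hours) of the analysis scales. The
#'   default grid spans 2-48 h at 12 voices per octave; the diel
#'   classification only needs periods 24, 12 and 8 h.
#' @param dt Sampling step in hours.
#' @param omega0 Morlet centre frequency.
#' @return An object of class `morlet_cwt`: a list with `power` (time x
#'   scale matrix), `periods`, `n`, `dt`, `omega0`, `variance` of `x`, and
#'   `coi_period`, the largest period unaffected by edge effects at each
#'   time step (e-folding cone of influence).
#' @export
morlet_cwt <- function(x, periods = diel_period_grid(), dt = 1, omega0 = 6) {
  n <- length(x)
  if (anyNA(x)) stop("series contains NA")
  if (n < 2 * max(periods) / dt) {
    stop("series shorter than twice the largest analysis period")
  }
  x0 <- x - mean(x)
  np <- 2L * 2L^ceiling(log2(n))
  xf <- stats::fft(c(x0, rep(0, np - n)))
  scales <- periods / fourier_factor(omega0)
  psi <- morlet_daughters(np, dt, scales, omega0)
  power <- vapply(seq_along(scales), function(j) {
    w <- stats::fft(xf * psi[, j], inverse = TRUE)[seq_len(n)] / np
    Re(w)^2 + Im(w)^2
  }, numeric(n))
  dist_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  structure(list(
    power = power, periods = periods, n = n, dt = dt, omega0 = omega0,
    variance = stats::var(x),
    coi_period = fourier_factor(omega0) * dist_edge / sqrt(2)
  ), class = "morlet_cwt")
}

#' Default scale grid for diel wavelet analysis
#'
#' Periods from 2 to 48 hours at 12 voices per octave, bracketing the
#' 1-3 cycles/day band with margin.
#' @return Numeric vector of periods in hours.
#' @export
diel_period_grid <- function() 2 * 2^seq(0, log2(24), by = 1 / 12)

#' @export
print.morlet_cwt <- function(x, ...) {
  cat("Morlet wavelet power spectrum\n")
  cat(sprintf("  %d time steps (dt = %g h), %d scales (%.3g-%.3g h), omega0 = %g\n",
              x$n, x$dt, length(x$periods), min(x$periods), max(x$periods),
              x$omega0))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' White-noise bootstrap significance thresholds for wavelet power
#'
#' Simulates Gaussian white-noise surrogate series of matched length and
#' variance, computes their wavelet power at the requested periods, and
#' returns the pointwise (1 - alpha) quantile of power per period, pooled
#' over surrogates and over the time steps outside the cone of influence.
#' Because the wavelet transform is linear and the null is Gaussian white
#' noise, thresholds scale exactly in proportion to the null variance;
#' [scale_null()] exploits this to reuse one set of surrogates across
#' series that differ only in variance.
#'
#' @param variance Variance of the analyzed series (must be > 0).
#' @param n Length of the analyzed series.
#' @param periods Periods (hours) at which thresholds are needed.
#' @param n_surrogates Number of white-noise surrogates.
#' @param alpha Pointwise significance level.
#' @param seed Integer seed; required, so thresholds are reproducible.
#' @param dt,omega0 Passed to the wavelet transform.
#' @return An object of class `wavelet_null`: list with `thresholds`
#'   (named by period), `periods`, `variance`, `n`, `n_surrogates`,
#'   `alpha`, `seed`.
#' @export
bootstrap_thresholds <- function(variance, n, periods = c(24, 12, 8),
                                 n_surrogates = 1000, alpha = 0.05, seed,
                                 dt = 1, omega0 = 6) {
  if (!is.finite(variance) || variance <= 0) {
    stop("variance must be a positive number (constant series have no null)")
  }
  if (missing(seed)) stop("seed is required")
  np <- 2L * 2L^ceiling(log2(n))
  scales <- periods / fourier_factor(omega0)
  psi <- morlet_daughters(np, dt, scales, omega0)
  dist_edge <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  interior <- lapply(periods, function(p) {
    which(fourier_factor(omega0) * dist_edge / sqrt(2) >= p)
  })
  sdx <- sqrt(variance)
  pools <- lapply(interior, function(idx) {
    matrix(NA_real_, length(idx), n_surrogates)
  })
  with_seed(seed, {
    for (b in seq_len(n_surrogates)) {
      z <- stats::rnorm(n, sd = sdx)
      zf <- stats::fft(c(z - mean(z), rep(0, np - n)))
      for (j in seq_along(periods)) {
        w <- stats::fft(zf * psi[, j], inverse = TRUE)[interior[[j]]] / np
        pools[[j]][, b] <- Re(w)^2 + Im(w)^2
      }
    }
  })
  thr <- vapply(pools, function(m) {
    stats::quantile(m, probs = 1 - alpha, names = FALSE)
  }, numeric(1))
  structure(list(
    thresholds = stats::setNames(thr, periods), periods = periods,
    variance = variance, n = n, n_surrogates = n_surrogates,
    alpha = alpha, seed = seed, dt = dt, omega0 = omega0
  ), class = "wavelet_null")
}

#' Rescale a wavelet null to a different series variance
#'
#' For Gaussian white noise, a series with variance `v` equals `sqrt(v)`
#' times a unit-variance series in distribution, and wavelet power is
#' quadratic in the series, so every power quantile scales exactly by `v`.
#'
#' @param null A `wavelet_null` object.
#' @param variance Target variance.
#' @return A `wavelet_null` with rescaled thresholds.
#' @export
scale_null <- function(null, variance) {
  stopifnot(inherits(null, "wavelet_null"), variance > 0)
  null$thresholds <- null$thresholds * variance / null$variance
  null$variance <- variance
  null
}

#' @export
print.wavelet_null <- function(x, ...) {
  cat(sprintf(
    "White-noise wavelet null: %d surrogates, n = %d, variance = %.4g, alpha = %g\n",
    x$n_surrogates, x$n, x$variance, x$alpha))
  print(round(x$thresholds, 4))
  invisible(x)
}

#' Classify hours as significantly periodic at diel frequencies
#'
#' An hour is classified as diel-periodic when the wavelet power at any of
#' the tested periods (by default 24, 12 and 8 h, i.e. 1, 2 and 3
#' cycles/day) exceeds that period's white-noise threshold. The tests are
#' pointwise at level alpha with no correction across the three periods:
#' the union ("any of") rule is the definition of the classification.
#'
#' @param cw A `morlet_cwt` object whose periods include the null's.
#' @param null A `wavelet_null` object.
#' @return `cw` with added elements `sig` (time x tested-period logical
#'   matrix), `diel_hourly` (logical vector) and `null`.
#' @export
classify_diel_hours <- function(cw, null) {
  stopifnot(inherits(cw, "morlet_cwt"), inherits(null, "wavelet_null"))
  idx <- match(null$periods, cw$periods)
  if (anyNA(idx)) {
    stop("wavelet transform lacks the null's periods: ",
         paste(null$periods[is.na(idx)], collapse = ", "))
  }
  sig <- sweep(cw$power[, idx, drop = FALSE], 2, null$thresholds, ">")
  colnames(sig) <- as.character(null$periods)
  cw$sig <- sig
  cw$diel_hourly <- rowSums(sig) > 0
  cw$null <- null
  cw
}

#' Daily movement predictability from classified hours
#'
#' MP for a day is the proportion of its 24 hours classified as
#' significantly diel-periodic. Days with fewer than 24 hours in the
#' series are excluded.
#'
#' @param cw A classified `morlet_cwt` (see [classify_diel_hours()]).
#' @param dates Local day of each hourly time step (length `cw$n`).
#' @return A tibble with columns `date`, `mp` and `edge` (TRUE when any
#'   hour of the day lies inside the 24-h cone of influence; informational,
#'   such days are not dropped).
#' @export
daily_mp <- function(cw, dates) {
  if (is.null(cw$diel_hourly)) stop("run classify_diel_hours() first")
  stopifnot(length(dates) == cw$n)
  df <- tibble::tibble(date = dates, sig = cw$diel_hourly,
                       inside_coi = cw$coi_period < 24)
  out <- dplyr::summarise(dplyr::group_by(df, .data$date),
                          n_hours = dplyr::n(),
                          mp = mean(.data$sig),
                          edge = any(.data$inside_coi),
                          .groups = "drop")
  out <- out[out$n_hours == 24, ]
  out$n_hours <- NULL
  out
}

#' Movement predictability for every individual-day
#'
#' Full spectral pipeline: per individual, the hourly displacement series
#' is trimmed to its complete local days, min-max normalized within each
#' day, wavelet-transformed at the diel periods, compared against a
#' white-noise bootstrap null whose variance matches that individual's
#' normalized series, and summarized as the daily proportion of
#' significant hours. A constant (zero-variance) series has no periodic
#' structure by definition and gets MP = 0 on all its days.
#'
#' @param disp Output of [hourly_displacements()] (any number of
#'   individuals).
#' @param alpha Pointwise significance level.
#' @param n_surrogates Surrogates for the bootstrap null.
#' @param seed Integer seed for the bootstrap (required).
#' @param periods Diel periods tested (hours).
#' @param share_null Reuse one unit-variance set of surrogates for all
#'   individuals with equal series length, rescaling thresholds to each
#'   individual's variance (exact for the Gaussian null; see
#'   [scale_null()]). Set to `FALSE` to draw a separate null per
#'   individual.
#' @return A tibble with columns `individual_id`, `date`, `mp`, `edge`.
#' @export
movement_predictability <- function(disp, alpha = 0.05, n_surrogates = 1000,
                                    seed, periods = c(24, 12, 8),
                                    share_null = TRUE) {
  if (missing(seed)) stop("seed is required")
  disp <- normalize_daily(disp)
  null_cache <- new.env(parent = emptyenv())
  out <- lapply(split(disp, disp$individual_id), function(g) {
    g <- g[order(g$timestamp), ]
    g <- g[!is.na(g$norm), ] # complete days only; contiguous by construction
    if (nrow(g) < 2 * max(periods)) return(NULL)
    v <- stats::var(g$norm)
    if (v == 0) {
      dts <- unique(g$date)
      return(tibble::tibble(individual_id = g$individual_id[1], date = dts,
                            mp = 0, edge = NA))
    }
    cw <- morlet_cwt(g$norm, periods)
    null <- if (share_null) {
      key <- as.character(nrow(g))
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- bootstrap_thresholds(
          variance = 1, n = nrow(g), periods = periods,
          n_surrogates = n_surrogates, alpha = alpha, seed = seed)
      }
      scale_null(null_cache[[key]], v)
    } else {
      bootstrap_thresholds(variance = v, n = nrow(g), periods = periods,
                           n_surrogates = n_surrogates, alpha = alpha,
                           seed = seed)
    }
    cw <- classify_diel_hours(cw, null)
    mp <- daily_mp(cw, g$date)
    tibble::tibble(individual_id = g$individual_id[1], mp)
  })
  dplyr::bind_rows(out)
}

#' Merge daily MP values into diel records
#'
#' @param records Output of [diel_displacement()].
#' @param mp Output of [movement_predictability()].
#' @return `records` with an `mp` column (NA where MP was not computable).
#' @export
add_mp <- function(records, mp) {
  records$mp <- NULL
  dplyr::left_join(records, mp[, c("individual_id", "date", "mp")],
                   by = c("individual_id", "date"))
}
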