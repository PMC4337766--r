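test_that("daily normalization rescales each day to [0, 1]", {
  v <- seq(2, 10, length.out = 24)
  d <- normalize_daily(make_disp(v))
  expect_equal(d$norm, (v - 2) / 8)

  # constant day maps to zeros
  d <- normalize_daily(make_disp(rep(3, 24)))
  expect_equal(d$norm, rep(0, 24))

  # invariant to positive rescaling of the raw values
  set.seed(2)
  v <- rexp(96)
  expect_equal(normalize_daily(make_disp(v))$norm,
               normalize_daily(make_disp(v * 13.7))$norm)
})

test_that("Fourier spectrum is normalized to unit white-noise power", {
  set.seed(5)
  sp <- fourier_spectrum(rnorm(4096))
  expect_gt(mean(sp$power), 0.9)
  expect_lt(mean(sp$power), 1.1)
  expect_true(all(sp$power >= 0))
  expect_error(fourier_spectrum(rnorm(40)), "48")
})

test_that("Fourier spectrum locates diel harmonics", {
  h <- seq_len(480)
  sp <- fourier_spectrum(sin(2 * pi * h / 24))
  expect_equal(sp$freq_cpd[which.max(sp$power)], 1, tolerance = 0.11)

  # 24-h plus 12-h components: local maxima at 1 and 2 cycles/day
  sp <- fourier_spectrum(sin(2 * pi * h / 24) + 0.7 * sin(2 * pi * h / 12))
  near <- function(f) sp$power[abs(sp$freq_cpd - f) < 0.3]
  away <- sp$power[abs(sp$freq_cpd - 1) > 0.3 & abs(sp$freq_cpd - 2) > 0.3]
  expect_gt(max(near(1)), max(away))
  expect_gt(max(near(2)), max(away))
})

test_that("FFT wavelet power matches the direct-convolution oracle", {
  set.seed(9)
  x <- rnorm(256)
  periods <- c(24, 12, 8)
  cw <- morlet_cwt(x, periods)
  oracle <- cwt_direct_oracle(x, periods)
  rel <- abs(cw$power - oracle) / pmax(oracle, max(oracle) * 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("wavelet power concentrates at the driving period", {
  x <- sin(2 * pi * seq_len(480) / 24)
  cw <- morlet_cwt(x, c(24, 12, 8))
  interior <- 80:400
  expect_true(all(cw$power[interior, 1] > cw$power[interior, 3]))

  # zero series: zero power
  cw0 <- morlet_cwt(rep(0, 200), c(24, 12, 8))
  expect_equal(max(cw0$power), 0)

  expect_error(morlet_cwt(rnorm(40), c(24, 12, 8)), "twice the largest")
})

test_that("bootstrap thresholds behave as quantiles of the null", {
  thr05 <- bootstrap_thresholds(1, 600, n_surrogates = 100, alpha = 0.05,
                                seed = 4)
  thr01 <- bootstrap_thresholds(1, 600, n_surrogates = 100, alpha = 0.01,
                                seed = 4)
  thr1 <- bootstrap_thresholds(1, 600, n_surrogates = 100, alpha = 1,
                               seed = 4)
  expect_true(all(thr01$thresholds > thr05$thresholds))
  expect_true(all(thr1$thresholds < thr05$thresholds / 50))

  # power is quadratic in the signal: thresholds scale linearly in variance
  thr2 <- bootstrap_thresholds(2, 600, n_surrogates = 100, alpha = 0.05,
                               seed = 4)
  expect_equal(thr2$thresholds, 2 * thr05$thresholds, tolerance = 1e-12)
  expect_equal(scale_null(thr05, 2)$thresholds, thr2$thresholds,
               tolerance = 1e-12)

  expect_error(bootstrap_thresholds(0, 600, seed = 1), "positive")
  expect_error(bootstrap_thresholds(1, 600), "seed")
})

test_that("hour classification applies the any-of-three-periods union rule", {
  set.seed(31)
  x <- rnorm(600)
  cw <- morlet_cwt(x, c(24, 12, 8))
  null <- bootstrap_thresholds(var(x), 600, n_surrogates = 100, alpha = 0.05,
                               seed = 8)
  # force huge thresholds: nothing significant
  big <- null; big$thresholds <- null$thresholds * 1e6
  expect_false(any(classify_diel_hours(cw, big)$diel_hourly))

  # strong 24-h sinusoid: nearly all interior hours significant
  xs <- sin(2 * pi * seq_len(600) / 24) + rnorm(600, sd = 0.1)
  cws <- morlet_cwt(xs, c(24, 12, 8))
  nulls <- bootstrap_thresholds(var(xs), 600, n_surrogates = 100,
                                alpha = 0.05, seed = 8)
  cls <- classify_diel_hours(cws, nulls)
  interior <- which(cls$coi_period >= 24)
  expect_gt(mean(cls$diel_hourly[interior]), 0.95)
})

test_that("white-noise classification rate sits between alpha and the union bound", {
  null <- bootstrap_thresholds(1, 2400, n_surrogates = 150, alpha = 0.05,
                               seed = 12)
  set.seed(13)
  rates <- replicate(30, {
    z <- rnorm(2400)
    cls <- classify_diel_hours(morlet_cwt(z, c(24, 12, 8)),
                               scale_null(null, var(z)))
    mean(cls$diel_hourly[cls$coi_period >= 24])
  })
  # union of three nearly independent pointwise tests at alpha = 0.05:
  # above the single-test rate, at or below ~1 - (1 - alpha)^3
  expect_gt(mean(rates), 0.05)
  expect_lt(mean(rates), 0.15)
})

test_that("per-scale false-positive rate is calibrated at alpha", {
  null <- bootstrap_thresholds(1, 2400, n_surrogates = 200, alpha = 0.05,
                               seed = 21)
  set.seed(22)
  rates <- sapply(1:60, function(i) {
    z <- rnorm(2400)
    cw <- morlet_cwt(z, c(24, 12, 8))
    thr <- scale_null(null, var(z))$thresholds
    vapply(1:3, function(j) {
      interior <- cw$coi_period >= cw$periods[j]
      mean(cw$power[interior, j] > thr[j])
    }, numeric(1))
  })
  for (j in 1:3) {
    expect_gt(mean(rates[j, ]), 0.04)
    expect_lt(mean(rates[j, ]), 0.06)
  }
})

test_that("daily MP is the proportion of significant hours", {
  d <- make_disp(rep(1, 72))
  cw <- morlet_cwt(rnorm(72), c(24, 12, 8))
  cw$diel_hourly <- c(rep(TRUE, 24), rep(FALSE, 24), rep(c(TRUE, FALSE), 12))
  mp <- daily_mp(cw, d$date)
  expect_equal(mp$mp, c(1, 0, 0.5))

  # incomplete day excluded
  dates <- c(d$date[1:60], rep(d$date[60] + 2, 12))
  mp <- daily_mp(cw, dates)
  expect_equal(nrow(mp), 2)
})

test_that("MP pipeline is invariant to rescaling raw displacements", {
  set.seed(41)
  v <- rexp(24 * 30)
  d1 <- make_disp(v)
  d2 <- make_disp(v * 5.5)
  mp1 <- movement_predictability(d1, n_surrogates = 100, seed = 6)
  mp2 <- movement_predictability(d2, n_surrogates = 100, seed = 6)
  expect_equal(mp1, mp2)
})

test_that("MP is near one on template days and near zero on noise days", {
  set.seed(43)
  tpl <- dielmove:::diurnal_template()
  periodic <- as.vector(vapply(1:40, function(i) tpl * rlnorm(24, 0, 0.15),
                               numeric(24)))
  noise <- rlnorm(24 * 40, 0, 0.8)
  mp_p <- movement_predictability(make_disp(periodic), n_surrogates = 150,
                                  seed = 14)
  mp_n <- movement_predictability(make_disp(noise), n_surrogates = 150,
                                  seed = 14)
  expect_gt(mean(mp_p$mp[!mp_p$edge]), 0.8)
  expect_lt(mean(mp_n$mp[!mp_n$edge]), 0.3)
  # MP stays in [0, 1] and is deterministic given the seed
  expect_true(all(mp_p$mp >= 0 & mp_p$mp <= 1))
  mp_p2 <- movement_predictability(make_disp(periodic), n_surrogates = 150,
                                   seed = 14)
  expect_equal(mp_p, mp_p2)
})

test_that("a constant displacement series has MP zero", {
  mp <- movement_predictability(make_disp(rep(2, 24 * 10)),
                                n_surrogates = 50, seed = 3)
  expect_equal(mp$mp, rep(0, 10))
})

test_that("mean MP never decreases with the embedded diel amplitude", {
  set.seed(51)
  base_noise <- rnorm(24 * 30)
  h <- seq_len(24 * 30)
  mean_mp <- vapply(c(0, 0.5, 1, 2, 4), function(a) {
    v <- a * (1 + sin(2 * pi * h / 24)) + exp(base_noise * 0.5)
    mp <- movement_predictability(make_disp(v), n_surrogates = 100, seed = 9)
    mean(mp$mp)
  }, numeric(1))
  expect_true(all(diff(mean_mp) >= -1e-9))
})
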