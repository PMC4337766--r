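# simulate model rows with known coefficients, optionally without
# individual heterogeneity
sim_rows <- function(seed, n_days = 300, response = "dd", ranef_sd = 0.15,
                     resid_sd = 0.8) {
  cfg <- sim_config(seed = seed, n_days = n_days,
                    dd_ranef_sd = if (response == "dd") ranef_sd else 0.15,
                    mp_ranef_sd = if (response == "mp") ranef_sd else 0.2,
                    dd_resid_sd = resid_sd)
  truth_model_rows(simulate_daily_responses(cfg), response)
}

test_that("with no individual heterogeneity the GLMM matches a plain GLM", {
  rows <- sim_rows(seed = 61, n_days = 400, response = "dd", ranef_sd = 0)
  fit <- fit_diel_glmm(rows, "dd")
  ols <- lm(y ~ ndvi * rank + lag1 + lag2, data = rows)
  expect_lt(fit$ranef_var, 1e-6)
  expect_equal(stats::setNames(fit$coefficients$estimate,
                               fit$coefficients$term),
               coef(ols)[fit$coefficients$term], tolerance = 1e-4)

  rows <- sim_rows(seed = 62, n_days = 400, response = "mp", ranef_sd = 0)
  fit <- fit_diel_glmm(rows, "mp")
  rows$.succ <- round(rows$y * 24)
  glm0 <- glm(cbind(.succ, 24 - .succ) ~ ndvi * rank + lag1 + lag2,
              data = rows, family = binomial())
  expect_equal(stats::setNames(fit$coefficients$estimate,
                               fit$coefficients$term),
               coef(glm0)[fit$coefficients$term], tolerance = 1e-4)
})

test_that("simulation-refit recovers generating coefficients within 3 SE", {
  # DD model, three seeds: demand all fixed effects inside 3 SE in at
  # least two, and the NDVI slope inside 3 SE in all three
  truth <- c(`(Intercept)` = 1.04, ndvi = 0.38, rankmedium = 0.08,
             rankvariable = -0.05, rankhigh = -0.18,
             `ndvi:rankmedium` = -0.05, `ndvi:rankvariable` = 0.02,
             `ndvi:rankhigh` = 0.23, lag1 = 0.19, lag2 = 0.31)
  hits <- vapply(c(71, 72, 73), function(s) {
    fit <- fit_diel_glmm(sim_rows(seed = s, n_days = 500), "dd")
    cf <- fit$coefficients
    z <- abs(cf$estimate - truth[cf$term]) / cf$se
    c(all(z < 3), z[cf$term == "ndvi"] < 3)
  }, logical(2))
  expect_gte(sum(hits[1, ]), 2)
  expect_true(all(hits[2, ]))
})

test_that("rank slopes add the interaction coefficients to the NDVI slope", {
  expect_equal(rank_slopes(table_dd_coef_named()),
               c(low = 0.38, medium = 0.33, variable = 0.40, high = 0.61))
  expect_equal(rank_slopes(table_mp_coef_named()),
               c(low = 2.85, medium = 2.07, variable = 2.31, high = 1.37))
  # all-zero interactions: identical slopes
  cf <- c(ndvi = 1.2, `ndvi:rankmedium` = 0, `ndvi:rankvariable` = 0,
          `ndvi:rankhigh` = 0)
  expect_true(all(rank_slopes(cf) == 1.2))
  expect_error(rank_slopes(c(intercept = 1)), "ndvi")
})

test_that("high-vs-low slope contrast is reported to the nearest percent", {
  expect_equal(unname(slope_percent_change(rank_slopes(table_dd_coef_named()))),
               61)
  expect_equal(unname(slope_percent_change(rank_slopes(table_mp_coef_named()))),
               -52)
  expect_equal(unname(slope_percent_change(c(low = 1.5, high = 1.5))), 0)
  expect_error(slope_percent_change(c(low = 0, high = 1)), "zero")
})

test_that("likelihood-ratio tests compare nested fits", {
  rows <- sim_rows(seed = 81, n_days = 200)
  full <- fit_diel_glmm(rows, "dd")
  main <- fit_diel_glmm(rows, "dd", terms = c("ndvi", "rank", "lag1", "lag2"))

  same <- lrt(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  res <- lrt(full, main)
  expect_equal(res$df, 3) # three interaction dummies
  expect_gte(res$chi2, 0)

  # adding a nested term never decreases the maximized log-likelihood
  expect_gte(full$loglik, main$loglik - 1e-6)

  only_lags <- fit_diel_glmm(rows, "dd", terms = c("lag1", "lag2"))
  only_ndvi <- fit_diel_glmm(rows, "dd", terms = "ndvi")
  expect_error(lrt(only_lags, only_ndvi), "not nested")
  mp_fit <- fit_diel_glmm(sim_rows(seed = 81, n_days = 200, response = "mp"),
                          "mp")
  expect_error(lrt(full, mp_fit), "response or link")
})

test_that("a strongly simulated interaction is detected by the LRT", {
  cfg <- sim_config(seed = 83, n_days = 400,
                    dd_coef = replace(default_dd_coefficients(),
                                      "ndvi_rank_high", 1.5))
  rows <- truth_model_rows(simulate_daily_responses(cfg), "dd")
  full <- fit_diel_glmm(rows, "dd")
  main <- fit_diel_glmm(rows, "dd", terms = c("ndvi", "rank", "lag1", "lag2"))
  expect_lt(lrt(full, main)$p_value, 0.01)
})

test_that("the LRT ladder reproduces the reported comparison structure", {
  rows <- sim_rows(seed = 85, n_days = 150)
  ladder <- lrt_ladder(rows, "dd")
  expect_equal(ladder$test, c("full_vs_null", "interaction", "lag1", "lag2"))
  expect_equal(ladder$df, c(9, 3, 1, 1))
  expect_true(all(ladder$chi2 >= 0))
})

test_that("identity-link fits are equivariant under response shifts", {
  rows <- sim_rows(seed = 95, n_days = 200)
  base <- fit_diel_glmm(rows, "dd")
  shifted <- rows
  c0 <- 5
  shifted$y <- rows$y + c0
  shifted$lag1 <- rows$lag1 + c0
  shifted$lag2 <- rows$lag2 + c0
  fit2 <- fit_diel_glmm(shifted, "dd")
  cf1 <- stats::setNames(base$coefficients$estimate, base$coefficients$term)
  cf2 <- stats::setNames(fit2$coefficients$estimate, fit2$coefficients$term)
  # slopes unchanged; intercept moves by c * (1 - phi1 - phi2)
  expect_equal(cf2[names(cf1) != "(Intercept)"],
               cf1[names(cf1) != "(Intercept)"], tolerance = 1e-6)
  expect_equal(cf2[["(Intercept)"]],
               cf1[["(Intercept)"]] + c0 * (1 - cf1[["lag1"]] - cf1[["lag2"]]),
               tolerance = 1e-6)
})

test_that("degenerate designs raise errors", {
  rows <- sim_rows(seed = 87, n_days = 100)
  rows$ndvi <- 0.4 # constant NDVI: collinear with the intercept
  expect_error(fit_diel_glmm(rows, "dd"), "collinear")
  one <- sim_rows(seed = 87, n_days = 100)
  expect_error(fit_diel_glmm(one[one$individual_id == "F01", ], "dd"),
               "two individuals")
  bad <- sim_rows(seed = 87, n_days = 100, response = "mp")
  bad$y[1] <- 1.4
  expect_error(fit_diel_glmm(bad, "mp"), "\\[0, 1\\]")
})

test_that("population predictions follow the link and the rank slopes", {
  rows <- sim_rows(seed = 91, n_days = 300, response = "mp")
  fit <- fit_diel_glmm(rows, "mp")
  pred <- predict_response(fit, ndvi_grid = seq(min(rows$ndvi),
                                                max(rows$ndvi),
                                                length.out = 7))
  expect_true(all(pred$predicted > 0 & pred$predicted < 1))

  # at fixed lags, the NDVI response ordering across ranks matches the
  # linear-scale slope ordering (logit is monotone)
  slopes <- rank_slopes(fit)
  d <- predict_response(fit, ndvi_grid = c(0.3, 0.5))
  gain <- vapply(split(d, d$rank), function(g) {
    diff(qlogis(g$predicted[order(g$ndvi)]))
  }, numeric(1))
  expect_equal(order(gain[names(slopes)]), order(slopes))

  expect_warning(predict_response(fit, ndvi_grid = 5), "outside")

  # identity link: predictions are linear in NDVI with the rank slope
  dd_fit <- fit_diel_glmm(sim_rows(seed = 92, n_days = 300), "dd")
  pd <- predict_response(dd_fit, ndvi_grid = c(0.2, 0.4), lag_values = c(2, 2))
  gain <- vapply(split(pd, pd$rank), function(g) diff(g$predicted) / 0.2,
                 numeric(1))
  expect_equal(gain[names(rank_slopes(dd_fit))],
               rank_slopes(dd_fit), tolerance = 1e-8)
})
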