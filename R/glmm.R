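#' Fit a diel movement mixed model
#'
#' Fits the random-intercept generalized linear mixed model
#' \deqn{g(E[n_{i,j}]) = \beta_0 + \beta_1 \mathrm{NDVI}_i + rank_j +
#'   \mathrm{NDVI}_i{:}rank_j + \phi_1 n_{i-1,j} + \phi_2 n_{i-2,j} + b_j}
#' where \eqn{n_{i,j}} is the response of individual *j* on day *i* and
#' \eqn{b_j} is a Gaussian random intercept. For diel displacement the
#' link *g* is the identity (a linear mixed model, `lme4::lmer`, plain
#' maximum likelihood so that likelihood-ratio tests on fixed effects are
#' valid). For movement predictability *g* is the logit: the daily
#' proportion is modelled as `mp * trials` successes out of `trials = 24`
#' hours via a binomial mixed model (`lme4::glmer`, Laplace
#' approximation), with the lag covariates entering as proportions on the
#' linear-predictor scale. Rank uses reference level "low". No random
#' slopes are included.
#'
#' @param rows Model rows ([model_rows()] output or equivalent) with
#'   columns `individual_id`, `y`, `lag1`, `lag2`, `ndvi`, `rank`.
#' @param response `"dd"` or `"mp"`.
#' @param terms Fixed-effect terms to include (subset of the default;
#'   reduced models for likelihood-ratio testing are built this way). The
#'   intercept is always included.
#' @param trials Number of binomial trials per day for the MP model.
#' @return An object of class `diel_glmm`: list with `model` (the merMod),
#'   `response`, `link`, `terms`, `coefficients` (tibble: term, estimate,
#'   se, statistic), `ranef_var`, `ranef` (per-individual intercepts),
#'   `loglik`, `n`, `n_fixef`, `converged`.
#' @export
fit_diel_glmm <- function(rows, response = c("dd", "mp"),
                          terms = c("ndvi", "rank", "ndvi:rank",
                                    "lag1", "lag2"),
                          trials = 24) {
  response <- match.arg(response)
  need <- c("individual_id", "y", "lag1", "lag2")
  if (any(c("ndvi", "rank", "ndvi:rank") %in% terms)) {
    need <- c(need, intersect(c("ndvi", "rank"), unlist(strsplit(terms, ":"))))
  }
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop("rows lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(rows$individual_id)) < 2) {
    stop("need at least two individuals to fit a mixed model")
  }
  if ("rank" %in% names(rows)) {
    rows$rank <- factor(as.character(rows$rank),
                        levels = intersect(rank_levels(),
                                           as.character(unique(rows$rank))))
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fixed_formula <- stats::as.formula(paste("y ~", rhs))
  X <- stats::model.matrix(fixed_formula, data = rows)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  if (response == "dd") {
    form <- stats::as.formula(paste("y ~", rhs, "+ (1 | individual_id)"))
    fit <- lme4::lmer(form, data = rows, REML = FALSE)
    link <- "identity"
  } else {
    if (any(rows$y < 0 | rows$y > 1)) stop("mp responses must lie in [0, 1]")
    rows$.succ <- round(rows$y * trials)
    rows$.fail <- trials - rows$.succ
    form <- stats::as.formula(
      paste("cbind(.succ, .fail) ~", rhs, "+ (1 | individual_id)"))
    fit <- lme4::glmer(form, data = rows, family = stats::binomial())
    link <- "logit"
  }
  sm <- summary(fit)$coefficients
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", unlist(msgs), ignore.case = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    model = fit,
    response = response,
    link = link,
    terms = terms,
    trials = if (response == "mp") trials else NA_integer_,
    coefficients = tibble::tibble(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      statistic = sm[, 3]),
    ranef_var = vc$vcov[vc$grp == "individual_id"],
    ranef = lme4::ranef(fit)$individual_id,
    loglik = as.numeric(stats::logLik(fit)),
    n = nrow(rows),
    n_fixef = ncol(X),
    converged = converged
  ), class = "diel_glmm")
}

#' @export
print.diel_glmm <- function(x, ...) {
  cat(sprintf("Diel %s model (%s link), %d rows, logLik = %.2f%s\n",
              toupper(x$response), x$link, x$n, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("Random-intercept variance: %.4g\n", x$ranef_var))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between nested diel models
#'
#' Twice the difference in maximized log-likelihood (clipped at zero)
#' against the chi-square distribution with degrees of freedom equal to
#' the difference in fixed-effect count. Both fits must use the same
#' response, link and data rows, and the reduced model's fixed terms must
#' be a subset of the full model's.
#'
#' @param full,reduced `diel_glmm` fits.
#' @return A tibble with columns `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "diel_glmm"), inherits(reduced, "diel_glmm"))
  if (full$response != reduced$response || full$link != reduced$link) {
    stop("models differ in response or link; not nested")
  }
  if (full$n != reduced$n) stop("models were fit to different row sets")
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested: reduced terms are not a subset")
  }
  df <- full$n_fixef - reduced$n_fixef
  if (df < 0) stop("models are not nested: reduced has more parameters")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, df = df, p_value = p)
}

#' NDVI slope per social rank
#'
#' The NDVI fixed-effect slope for the reference level ("low") plus, for
#' every other rank level, that level's NDVI interaction coefficient.
#'
#' @param fit A `diel_glmm` fit, or a named coefficient vector using terms
#'   `ndvi` and `ndvi:rank<level>`.
#' @return Named numeric vector of slopes, reference level first.
#' @export
rank_slopes <- function(fit) {
  if (inherits(fit, "diel_glmm")) {
    cf <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
    levels <- levels(stats::model.frame(fit$model)$rank)
  } else {
    cf <- fit
    levels <- c("low", sub("^ndvi:rank", "",
                           grep("^ndvi:rank", names(cf), value = TRUE)))
  }
  if (!"ndvi" %in% names(cf)) stop("fit has no 'ndvi' term")
  out <- stats::setNames(numeric(length(levels)), levels)
  out[1] <- cf["ndvi"]
  for (lev in levels[-1]) {
    term <- paste0("ndvi:rank", lev)
    if (!term %in% names(cf)) stop("missing interaction term: ", term)
    out[lev] <- cf["ndvi"] + cf[term]
  }
  out
}

#' Percent change of the high-rank NDVI slope over the low-rank slope
#'
#' @param slopes Named slope vector from [rank_slopes()] containing `low`
#'   and `high`.
#' @return Signed percent change, rounded to the nearest percent.
#' @export
slope_percent_change <- function(slopes) {
  if (!all(c("low", "high") %in% names(slopes))) {
    stop("slopes must contain 'low' and 'high'")
  }
  if (slopes["low"] == 0) stop("low-rank slope is zero; percent change undefined")
  round(100 * (slopes["high"] - slopes["low"]) / slopes["low"])
}

#' Population-level predicted response over an NDVI grid
#'
#' Predictions through the inverse link with the random intercept at its
#' population value (zero) and the two lag covariates held at supplied
#' values -- conventionally their across-individual median for diel
#' displacement and mean for movement predictability.
#'
#' @param fit A `diel_glmm` fit.
#' @param ndvi_grid NDVI values at which to predict.
#' @param lag_values Length-2 vector (lag1, lag2). Defaults to the median
#'   (DD) or mean (MP) of the fitted rows' lags.
#' @param ranks Rank levels to predict for (default: all fitted levels).
#' @return A tibble with columns `ndvi`, `rank`, `predicted`.
#' @export
predict_response <- function(fit, ndvi_grid, lag_values = NULL, ranks = NULL) {
  stopifnot(inherits(fit, "diel_glmm"))
  mf <- stats::model.frame(fit$model)
  if (is.null(lag_values)) {
    f <- if (fit$response == "dd") stats::median else mean
    lag_values <- c(f(mf$lag1), f(mf$lag2))
  }
  if (is.null(ranks)) ranks <- levels(mf$rank)
  fitted_range <- range(mf$ndvi)
  if (any(ndvi_grid < fitted_range[1] | ndvi_grid > fitted_range[2])) {
    warning("some NDVI values lie outside the fitted range; ",
            "predictions are extrapolations")
  }
  newdata <- expand.grid(ndvi = ndvi_grid, rank = factor(ranks,
                                                         levels = levels(mf$rank)),
                         KEEP.OUT.ATTRS = FALSE)
  newdata$lag1 <- lag_values[1]
  newdata$lag2 <- lag_values[2]
  pred <- stats::predict(fit$model, newdata = newdata, re.form = NA,
                         type = "response")
  tibble::tibble(ndvi = newdata$ndvi, rank = as.character(newdata$rank),
                 predicted = as.numeric(pred))
}

#' Likelihood-ratio test ladder for a diel model
#'
#' The sequence of nested comparisons reported for these models: the full
#' model against an intercept-plus-random-effect null, the NDVI x rank
#' interaction against main effects only, the first lag against no lags,
#' and the second lag against one lag.
#'
#' @param rows Model rows.
#' @param response `"dd"` or `"mp"`.
#' @return A tibble with one row per comparison (`test`, `chi2`, `df`,
#'   `p_value`).
#' @export
lrt_ladder <- function(rows, response = c("dd", "mp")) {
  response <- match.arg(response)
  full <- fit_diel_glmm(rows, response)
  f <- function(terms) fit_diel_glmm(rows, response, terms = terms)
  comparisons <- list(
    full_vs_null = list(full, f(character(0))),
    interaction = list(full, f(c("ndvi", "rank", "lag1", "lag2"))),
    lag1 = list(f(c("ndvi", "rank", "ndvi:rank", "lag1")),
                f(c("ndvi", "rank", "ndvi:rank"))),
    lag2 = list(full, f(c("ndvi", "rank", "ndvi:rank", "lag1")))
  )
  out <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    res <- lrt(cmp[[1]], cmp[[2]])
    tibble::tibble(test = nm, res)
  })
  dplyr::bind_rows(out)
}
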