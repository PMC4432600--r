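#' Fit a one-year cosinor model to a single feature
#'
#' Regresses a response measured at known calendar dates on `sin(2*pi*t)` and
#' `cos(2*pi*t)`, where `t` is the fraction of the year elapsed at the bleed
#' date (see [day_fraction()]), together with any fixed covariates and random
#' intercepts named in the [model_spec()]. With no random intercepts the fit
#' is ordinary least squares; otherwise a linear mixed model is fitted by
#' **maximum likelihood** (not REML) via [lme4::lmer()], so that likelihood
#' comparisons between the seasonal model and its null twin ([fit_null()])
#' and BIC-based model preference are valid.
#'
#' The fitted seasonal component is `r(t) = b_hat * sin(2*pi*t) +
#' c_hat * cos(2*pi*t)`: amplitude `sqrt(b^2 + c^2)` is half the
#' peak-to-trough range and the acrophase (peak time) is `atan2(b, c) /
#' (2*pi)` years.
#'
#' @param y numeric response vector (typically log2 expression), one value per
#'   row of `meta`.
#' @param meta data frame of sample metadata; must contain `date_of_bleed`
#'   plus any columns the spec's covariates and grouping keys resolve to.
#' @param spec a [model_spec()].
#' @return an object of class `cosinor_fit` with elements `b_hat`, `c_hat`,
#'   `coefficients`, `se`, `random_var`, `residual_var`, `loglik_ml`,
#'   `n_obs`, `n_params`, `bic` (`= n_params * log(n_obs) - 2 * loglik_ml`),
#'   `converged`, `method` (`"ols"` or `"ml_mixed"`) and, for OLS fits,
#'   `rss` and `rank`.
#' @seealso [fit_null()], [season_test()], [cosinor_screen()]
#' @examples
#' t <- (1:12) / 12
#' meta <- data.frame(date_of_bleed = as.Date("2009-01-01") + round(365 * t) - 1)
#' y <- 2 + sin(2 * pi * day_fraction(meta$date_of_bleed))
#' fit_cosinor(y, meta, model_spec())
#' @export
fit_cosinor <- function(y, meta, spec = model_spec()) {
  .fit_model(y, meta, spec, seasonal = TRUE)
}

#' Fit the no-season null model
#'
#' Identical to [fit_cosinor()] with the sine and cosine columns removed:
#' intercept, fixed covariates and random intercepts only. Used as the null
#' hypothesis in [season_test()] and as the comparison fit for BIC model
#' preference.
#'
#' @inheritParams fit_cosinor
#' @return a `cosinor_fit` with `b_hat = c_hat = NA`.
#' @export
fit_null <- function(y, meta, spec = model_spec()) {
  .fit_model(y, meta, spec, seasonal = FALSE)
}

#' Fit a climate-predictor alternative model
#'
#' Replaces the sine/cosine pair with a single measured environmental
#' exposure (e.g. mean temperature or sunlight hours over the week preceding
#' each bleed, see [weekly_mean_exposure()]), keeping the same covariates and
#' random intercepts, so the resulting fit is comparable with the cosinor fit
#' by log-likelihood or BIC.
#'
#' @inheritParams fit_cosinor
#' @param exposure numeric vector, one exposure value per sample.
#' @return a `cosinor_fit` whose `coefficients` include an `exposure` term;
#'   `b_hat`/`c_hat` are `NA`.
#' @export
fit_climate_predictor <- function(y, meta, exposure, spec = model_spec()) {
  .fit_model(y, meta, spec, seasonal = FALSE, exposure = exposure)
}

.lmer_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.conv.singular = "ignore",
                    calc.derivs = FALSE)
}

.fit_model <- function(y, meta, spec, seasonal = TRUE, exposure = NULL) {
  stopifnot(is.numeric(y))
  if (!is.data.frame(meta)) stop("meta must be a data frame")
  if (length(y) != nrow(meta)) stop("length(y) must equal nrow(meta)")
  y <- .apply_transform(y, spec$transform)
  if (!all(is.finite(y))) stop("non-finite response values")
  n <- length(y)
  if (n < 8L) stop("need at least 8 observations, got ", n)
  mf <- .build_model_frame(y, meta, spec, seasonal = seasonal,
                           exposure = exposure)
  rhs <- if (length(mf$rhs)) paste(mf$rhs, collapse = " + ") else "1"
  if (length(mf$rand) == 0L) {
    fit <- lm(as.formula(paste("y ~", rhs)), data = mf$dat)
    X <- model.matrix(fit)
    if (fit$rank < ncol(X)) {
      stop("rank-deficient design; aliased columns: ",
           paste(colnames(X)[is.na(coef(fit))], collapse = ", "))
    }
    rss <- sum(fit$residuals^2)
    ll <- as.numeric(logLik(fit))
    k <- fit$rank + 1L   # + residual variance
    co <- coef(fit)
    se <- suppressWarnings(sqrt(diag(vcov(fit))))
    out <- list(
      b_hat = if (seasonal) unname(co["sin_t"]) else NA_real_,
      c_hat = if (seasonal) unname(co["cos_t"]) else NA_real_,
      coefficients = co, se = se,
      random_var = numeric(0),
      residual_var = rss / n,   # ML estimate
      rss = rss, rank = fit$rank,
      loglik_ml = ll, n_obs = n, n_params = k,
      bic = k * log(n) - 2 * ll,
      converged = TRUE, method = "ols", seasonal = seasonal)
  } else {
    fml <- as.formula(paste(
      "y ~", rhs, "+",
      paste(sprintf("(1 | %s)", mf$rand), collapse = " + ")))
    fit <- suppressMessages(
      lme4::lmer(fml, data = mf$dat, REML = FALSE,
                 control = .lmer_control()))
    co <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    rv <- vc$vcov[vc$grp != "Residual"]
    names(rv) <- sub("^\\.g_", "", vc$grp[vc$grp != "Residual"])
    llo <- logLik(fit)
    k <- attr(llo, "df")
    msgs <- fit@optinfo$conv$lme4$messages
    out <- list(
      b_hat = if (seasonal) unname(co["sin_t"]) else NA_real_,
      c_hat = if (seasonal) unname(co["cos_t"]) else NA_real_,
      coefficients = co, se = sqrt(diag(as.matrix(vcov(fit)))),
      random_var = rv,
      residual_var = lme4::getME(fit, "sigma")^2,
      rss = NA_real_, rank = length(co),
      loglik_ml = as.numeric(llo), n_obs = n, n_params = k,
      bic = k * log(n) - 2 * as.numeric(llo),
      converged = fit@optinfo$conv$opt == 0 && is.null(msgs),
      method = "ml_mixed", seasonal = seasonal)
  }
  out$model <- fit
  class(out) <- "cosinor_fit"
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("cosinor_fit (%s, %s)\n", x$method,
              if (x$seasonal) "seasonal" else "null"))
  if (x$seasonal) {
    amp <- sqrt(x$b_hat^2 + x$c_hat^2)
    cat(sprintf("  b_hat = %.4f, c_hat = %.4f (amplitude %.4f)\n",
                x$b_hat, x$c_hat, amp))
  }
  cat(sprintf("  n = %d, logLik(ML) = %.3f, BIC = %.3f\n",
              x$n_obs, x$loglik_ml, x$bic))
  if (length(x$random_var)) {
    cat("  random-intercept variance(s): ",
        paste(sprintf("%s = %.4f", names(x$random_var), x$random_var),
              collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  residual variance (ML): %.4f\n", x$residual_var))
  invisible(x)
}

#' Test the effect of season by comparing nested fits
#'
#' Compares the seasonal cosinor fit with its null twin. For OLS fits the
#' comparison is the classical F-test, `F = ((RSS0 - RSS1)/2) /
#' (RSS1/(n - p))` with `(2, n - p)` degrees of freedom where `p` is the
#' number of regression coefficients of the seasonal model. For mixed-model
#' fits the comparison is a likelihood-ratio test, `2 * (logLik_seasonal -
#' logLik_null)` referred to a chi-square distribution with 2 degrees of
#' freedom (one for each of the sine and cosine coefficients). Both fits must
#' come from maximum likelihood on the same response and covariates.
#'
#' A p-value that underflows is clamped to the smallest representable
#' positive double rather than returned as an exact zero.
#'
#' @param fit_seasonal `cosinor_fit` from [fit_cosinor()].
#' @param fit_null `cosinor_fit` from [fit_null()] on the same data.
#' @return an object of class `season_test` with `statistic`, `df`
#'   (numerator df, always 2), `df2` (denominator df; `NA` for the LRT),
#'   `p_value` and `family` (`"F"` or `"LRT_chisq"`).
#' @export
season_test <- function(fit_seasonal, fit_null) {
  stopifnot(inherits(fit_seasonal, "cosinor_fit"),
            inherits(fit_null, "cosinor_fit"))
  if (!fit_seasonal$seasonal || fit_null$seasonal)
    stop("arguments must be (seasonal fit, null fit), in that order")
  if (fit_seasonal$n_obs != fit_null$n_obs)
    stop("fits are not on the same data (different n_obs)")
  if (fit_seasonal$method != fit_null$method)
    stop("fits use different estimation paths; refit with the same spec")
  df <- fit_seasonal$n_params - fit_null$n_params
  if (df != 2L)
    stop("non-nested inputs: seasonal model must add exactly the sin/cos pair")
  n <- fit_seasonal$n_obs
  if (fit_seasonal$method == "ols") {
    rss1 <- fit_seasonal$rss
    rss0 <- fit_null$rss
    if (rss0 < rss1 - 1e-8 * max(1, rss0))
      stop("null RSS below seasonal RSS: fits are not nested")
    p <- fit_seasonal$rank
    df2 <- n - p
    if (rss0 <= .Machine$double.eps * n) {
      stat <- 0; pv <- 1   # constant response: nothing to explain
    } else if (rss1 <= .Machine$double.eps * rss0) {
      stat <- Inf; pv <- 0
    } else {
      stat <- ((rss0 - rss1) / df) / (rss1 / df2)
      pv <- pf(stat, df, df2, lower.tail = FALSE)
    }
    family <- "F"
  } else {
    dll <- fit_seasonal$loglik_ml - fit_null$loglik_ml
    if (is.finite(dll) && dll < -1e-6 * max(1, abs(fit_null$loglik_ml)))
      stop("seasonal log-likelihood below null beyond tolerance: ",
           "optimizer failure")
    stat <- 2 * max(dll, 0)
    pv <- pchisq(stat, df = df, lower.tail = FALSE)
    df2 <- NA_real_
    family <- "LRT_chisq"
  }
  pv <- min(max(pv, .Machine$double.xmin), 1)
  structure(list(statistic = stat, df = df, df2 = df2, p_value = pv,
                 family = family),
            class = "season_test")
}

#' @export
print.season_test <- function(x, ...) {
  dfs <- if (is.na(x$df2)) sprintf("df = %d", x$df)
         else sprintf("df = (%d, %g)", x$df, x$df2)
  cat(sprintf("season test (%s): statistic = %.4g, %s, p = %.4g\n",
              x$family, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Mean exposure over the week preceding a date
#'
#' Averages a daily climate variable over the seven days strictly before each
#' query date (the window `[date - 7, date - 1]`), the exposure definition
#' used by the climate-predictor models.
#'
#' @param series a climate series data frame with a `date` column (see
#'   [simulate_climate()] / [read_climate_series()]).
#' @param dates query date(s).
#' @param var which series column to average (default `"tmean_c"`).
#' @return numeric vector of window means, one per query date.
#' @export
weekly_mean_exposure <- function(series, dates, var = "tmean_c") {
  stopifnot(is.data.frame(series), var %in% names(series))
  d <- as.Date(dates)
  sdate <- as.Date(series$date)
  vapply(d, function(dd) {
    window <- seq(dd - 7L, dd - 1L, by = "day")
    idx <- match(window, sdate)
    if (anyNA(idx)) {
      stop("climate series is missing ", sum(is.na(idx)),
           " day(s) in the week preceding ", format(dd))
    }
    mean(series[[var]][idx])
  }, numeric(1))
}
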