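#' Month-based cosinor model for a blood-count response
#'
#' For haematology tables where only the month of bleed is known: ordinary
#' least squares of the response on `sin(2*pi*month/12)` and
#' `cos(2*pi*month/12)` (no other covariates, no random intercepts — each
#' donor is observed once), with the effect of season assessed by the F-test
#' against the intercept-only model on `(2, n - 3)` degrees of freedom. The
#' month-to-time mapping `t = month/12` is periodic, so months recorded
#' modulo 12 (e.g. 13 for January) give identical fits.
#'
#' @param table an `fbc_table` or data frame with a `month` column (integers;
#'   interpreted modulo 12) and the response column.
#' @param response name of the response column.
#' @param transform optional response transform (`"identity"`, `"log"`,
#'   `"log2"`), e.g. `"log"` for right-skewed analytes.
#' @return an object of class `season_f_test`: `response`, `statistic`,
#'   `df1`, `df2`, `p_value`, `n`, plus the underlying `lm` fit as `$fit`.
#' @export
month_cosinor <- function(table, response, transform = "identity") {
  stopifnot(is.data.frame(table), "month" %in% names(table),
            response %in% names(table))
  y <- .apply_transform(as.numeric(table[[response]]), transform)
  if (!all(is.finite(y))) stop("non-finite response values")
  month <- as.numeric(table$month)
  if (length(unique(month %% 12)) < 3L)
    stop("need at least 3 distinct months (rank deficiency)")
  t <- month / 12
  dat <- data.frame(y = y, s = sin(2 * pi * t), c = cos(2 * pi * t))
  fit1 <- lm(y ~ s + c, data = dat)
  .f_vs_null(fit1, lm(y ~ 1, data = dat), df1 = 2L, response = response)
}

#' Fourier-harmonic seasonality model with spline age adjustment
#'
#' The model used for cohorts with richer covariates and a less sinusoidal
#' climate: the response is regressed on sex, a natural cubic spline in age,
#' and `k` Fourier harmonic pairs `sin(2*pi*h*t), cos(2*pi*h*t)` for
#' `h = 1..k` of the year fraction `t` (from the bleed date, or `month/12`).
#' Season is tested by the F-test of the `2k` harmonic columns against the
#' covariate-only model.
#'
#' @param table data frame with `date` (or `month`), `age`, `sex` and the
#'   response column.
#' @param response name of the response column.
#' @param k number of harmonics (default 3, i.e. 6 seasonal columns).
#' @param age_df degrees of freedom of the natural cubic age spline
#'   (default 4, i.e. 3 interior knots at age quantiles).
#' @param time `"date"` (year fraction via [day_fraction()]) or `"month"`
#'   (`t = month/12`).
#' @param covariates include the sex + age-spline adjustment (set `FALSE`
#'   to reduce, at `k = 1` and `time = "month"`, to [month_cosinor()]).
#' @param transform optional response transform.
#' @return a `season_f_test` (numerator df `2k`).
#' @export
fourier_season_model <- function(table, response, k = 3L, age_df = 4L,
                                 time = c("date", "month"),
                                 covariates = TRUE,
                                 transform = "identity") {
  time <- match.arg(time)
  k <- as.integer(k)
  stopifnot(is.data.frame(table), response %in% names(table), k >= 1L)
  y <- .apply_transform(as.numeric(table[[response]]), transform)
  if (!all(is.finite(y))) stop("non-finite response values")
  t <- if (time == "date") {
    if (!"date" %in% names(table)) stop("table has no date column")
    day_fraction(table$date)
  } else {
    if (!"month" %in% names(table)) stop("table has no month column")
    as.numeric(table$month) / 12
  }
  dat <- data.frame(y = y)
  seas <- character(0)
  for (h in seq_len(k)) {
    dat[[paste0("s", h)]] <- sin(2 * pi * h * t)
    dat[[paste0("c", h)]] <- cos(2 * pi * h * t)
    seas <- c(seas, paste0("s", h), paste0("c", h))
  }
  covs <- "1"
  if (covariates) {
    stopifnot(all(c("age", "sex") %in% names(table)))
    if (sd(as.numeric(table$age)) == 0)
      stop("age is constant: spline knots degenerate")
    dat$age <- as.numeric(table$age)
    dat$sex <- factor(table$sex)
    covs <- sprintf("sex + splines::ns(age, df = %d)", age_df)
  }
  f1 <- as.formula(paste("y ~", covs, "+", paste(seas, collapse = " + ")))
  f0 <- as.formula(paste("y ~", covs))
  .f_vs_null(lm(f1, data = dat), lm(f0, data = dat), df1 = 2L * k,
             response = response)
}

.f_vs_null <- function(fit1, fit0, df1, response) {
  n <- length(fit1$residuals)
  rss1 <- sum(fit1$residuals^2)
  rss0 <- sum(fit0$residuals^2)
  df2 <- n - fit1$rank
  if (rss0 <= .Machine$double.eps * n) {
    stat <- 0; pv <- 1
  } else if (rss1 <= .Machine$double.eps * rss0) {
    stat <- Inf; pv <- .Machine$double.xmin
  } else {
    stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    pv <- min(max(pf(stat, df1, df2, lower.tail = FALSE),
                  .Machine$double.xmin), 1)
  }
  structure(list(response = response, statistic = stat, df1 = df1,
                 df2 = df2, p_value = pv, n = n, fit = fit1),
            class = "season_f_test")
}

#' @export
print.season_f_test <- function(x, ...) {
  cat(sprintf("season F-test for '%s': F = %.4g on (%d, %d) df, p = %.4g (n = %d)\n",
              x$response, x$statistic, x$df1, x$df2, x$p_value, x$n))
  invisible(x)
}

#' Screen every response of a blood-count table for seasonality
#'
#' Convenience wrapper applying [month_cosinor()] or
#' [fourier_season_model()] to each response column.
#'
#' @param table an `fbc_table`.
#' @param responses response column names; defaults to every numeric column
#'   that is not `month` or `age`.
#' @param method `"month_cosinor"` or `"fourier"`.
#' @param ... passed to the per-response model function.
#' @return data frame: `response`, `statistic`, `df1`, `df2`, `p_value`,
#'   `n`.
#' @export
fbc_screen <- function(table, responses = NULL,
                       method = c("month_cosinor", "fourier"), ...) {
  method <- match.arg(method)
  if (is.null(responses)) {
    num <- vapply(table, is.numeric, logical(1))
    responses <- setdiff(names(table)[num], c("month", "age"))
  }
  rows <- lapply(responses, function(r) {
    ft <- if (method == "month_cosinor") month_cosinor(table, r, ...)
          else fourier_season_model(table, r, ...)
    data.frame(response = r, statistic = ft$statistic, df1 = ft$df1,
               df2 = ft$df2, p_value = ft$p_value, n = ft$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
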