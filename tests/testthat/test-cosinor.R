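test_that("day_fraction maps dates to ordinal-day / days-in-year", {
  expect_equal(day_fraction("2003-07-15"), 196 / 365)
  expect_equal(day_fraction("2003-01-15"), 15 / 365)
  expect_equal(day_fraction("2004-02-29"), 60 / 366)  # leap year
  expect_equal(day_fraction("2003-12-31"), 1)
  expect_error(day_fraction("not-a-date"), "unparseable")
})

test_that("noise-free sinusoid is interpolated exactly", {
  meta <- meta_frame(year_dates(12))
  t <- day_fraction(meta$date_of_bleed)
  fit <- fit_cosinor(2 + sin(2 * pi * t), meta)
  expect_equal(fit$b_hat, 1, tolerance = 1e-10)
  expect_equal(fit$c_hat, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 2,
               tolerance = 1e-10)
})

test_that("constant response gives zero seasonal coefficients", {
  meta <- meta_frame(year_dates(20))
  fit <- fit_cosinor(rep(3.7, 20), meta)
  expect_equal(fit$b_hat, 0, tolerance = 1e-10)
  expect_equal(fit$c_hat, 0, tolerance = 1e-10)
  fit0 <- fit_null(rep(3.7, 20), meta)
  expect_equal(unname(fit0$coefficients["(Intercept)"]), 3.7)
  expect_equal(fit0$residual_var, 0, tolerance = 1e-12)
})

test_that("OLS path matches the normal-equations oracle", {
  set.seed(41)
  meta <- meta_frame(year_dates(400))
  t <- day_fraction(meta$date_of_bleed)
  y <- 6 + 0.5 * sin(2 * pi * t) - 0.8 * cos(2 * pi * t) + rnorm(400, 0, 0.1)
  fit <- fit_cosinor(y, meta)
  X <- cbind(1, sin(2 * pi * t), cos(2 * pi * t))
  orc <- ols_oracle(X, y)
  expect_equal(fit$b_hat, orc$beta[2], tolerance = 1e-8)
  expect_equal(fit$c_hat, orc$beta[3], tolerance = 1e-8)
  expect_equal(fit$rss, orc$rss, tolerance = 1e-8)
  expect_lt(abs(fit$b_hat - 0.5), 0.05)
  expect_lt(abs(fit$c_hat - (-0.8)), 0.05)
  # null model RSS against the oracle too
  fit0 <- fit_null(y, meta)
  orc0 <- ols_oracle(cbind(rep(1, 400)), y)
  expect_equal(fit0$rss, orc0$rss, tolerance = 1e-8)
  expect_lte(fit0$loglik_ml, fit$loglik_ml)
})

test_that("season test: F statistic matches the closed-form oracle", {
  set.seed(42)
  meta <- meta_frame(year_dates(60))
  t <- day_fraction(meta$date_of_bleed)
  y <- 1 + 0.3 * cos(2 * pi * t) + rnorm(60, 0, 0.5)
  f1 <- fit_cosinor(y, meta)
  f0 <- fit_null(y, meta)
  st <- season_test(f1, f0)
  expect_identical(st$family, "F")
  expect_identical(st$df, 2L)
  expect_equal(st$statistic, f_oracle(f0$rss, f1$rss, 60, 3),
               tolerance = 1e-10)
  expect_equal(st$p_value,
               pf(st$statistic, 2, 57, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("perfect seasonal fit underflows to smallest positive p", {
  meta <- meta_frame(year_dates(24))
  t <- day_fraction(meta$date_of_bleed)
  y <- 0.7 * sin(2 * pi * t) + 0.2 * cos(2 * pi * t)
  st <- season_test(fit_cosinor(y, meta), fit_null(y, meta))
  expect_gt(st$p_value, 0)
  expect_lte(st$p_value, .Machine$double.xmin)
})

test_that("mixed-model LRT has 2 df and sane p-values", {
  cfg <- sim_config(n_subjects = 25, visits_per_subject = 4,
                    n_features = 1, frac_seasonal = 1,
                    amplitude_range = c(0.6, 0.6), acrophase_mode = "winter",
                    seed = 5)
  st <- simulate_cohort(cfg)
  spec <- model_spec(fixed = c("age", "sex"), random = "subject")
  f1 <- fit_cosinor(st$matrix[1, ], st$samples, spec)
  f0 <- fit_null(st$matrix[1, ], st$samples, spec)
  expect_identical(f1$method, "ml_mixed")
  expect_true("subject" %in% names(f1$random_var))
  tst <- season_test(f1, f0)
  expect_identical(tst$family, "LRT_chisq")
  expect_identical(tst$df, 2L)
  expect_lt(tst$p_value, 1e-6)
  expect_error(season_test(f0, f1), "seasonal fit, null fit")
})

test_that("mixed path reduces to OLS with one observation per subject", {
  set.seed(7)
  meta <- meta_frame(year_dates(80))   # distinct subject per sample
  t <- day_fraction(meta$date_of_bleed)
  y <- 5 + 0.4 * sin(2 * pi * t) + rnorm(80, 0, 0.3)
  f_ols <- fit_cosinor(y, meta, model_spec())
  f_mix <- fit_cosinor(y, meta, model_spec(random = "subject"))
  expect_equal(f_mix$b_hat, f_ols$b_hat, tolerance = 1e-8)
  expect_equal(f_mix$c_hat, f_ols$c_hat, tolerance = 1e-8)
  expect_equal(unname(f_mix$coefficients["(Intercept)"]),
               unname(f_ols$coefficients["(Intercept)"]), tolerance = 1e-8)
})

test_that("shifting all dates rotates (b, c) by 2*pi*k/365 (noise-free)", {
  meta <- meta_frame(year_dates(40, 2009))
  t <- day_fraction(meta$date_of_bleed)
  b <- 0.6; cc <- -0.3
  y <- b * sin(2 * pi * t) + cc * cos(2 * pi * t)
  for (k in c(10, 45, 120)) {
    meta2 <- meta
    meta2$date_of_bleed <- meta$date_of_bleed + k
    # keep within non-leap years so the denominator stays 365
    meta2$date_of_bleed <- as.Date(ifelse(
      format(meta2$date_of_bleed, "%Y") == "2009", meta2$date_of_bleed,
      meta2$date_of_bleed - 365), origin = "1970-01-01")
    fit <- fit_cosinor(y, meta2)
    th <- 2 * pi * k / 365
    expect_equal(fit$b_hat, b * cos(th) + cc * sin(th), tolerance = 1e-8)
    expect_equal(fit$c_hat, cc * cos(th) - b * sin(th), tolerance = 1e-8)
  }
})

test_that("rank deficiency and bad inputs are reported", {
  meta <- meta_frame(year_dates(20))
  meta$flat <- 1
  expect_error(fit_cosinor(c(NA, rnorm(19)), meta), "non-finite")
  expect_error(fit_cosinor(rnorm(5), meta[1:5, ]), "at least 8")
  meta$dup <- sin(2 * pi * day_fraction(meta$date_of_bleed))
  expect_error(fit_cosinor(rnorm(20), meta,
                           model_spec(fixed = "dup")), "aliased")
})

test_that("season-test p-values are uniform under the null (OLS screen)", {
  cfg <- sim_config(n_subjects = 200, visits_per_subject = 1,
                    n_features = 1000, frac_seasonal = 0, subject_sd = 0,
                    covariate_effects = c(age = 0, sex = 0), seed = 11)
  scr <- cosinor_screen(simulate_cohort(cfg), model_spec())
  ks <- suppressWarnings(ks.test(scr$p_season, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("amplitude sqrt(b^2+c^2) is recovered without material bias", {
  cfg <- sim_config(n_subjects = 400, visits_per_subject = 1,
                    n_features = 500, frac_seasonal = 1,
                    amplitude_range = c(0.5, 0.5), acrophase_mode = "uniform",
                    subject_sd = 0, residual_sd = 0.5,
                    covariate_effects = c(age = 0, sex = 0), seed = 13)
  scr <- cosinor_screen(simulate_cohort(cfg), model_spec())
  amp <- sqrt(scr$b_hat^2 + scr$c_hat^2)
  se_mc <- sd(amp) / sqrt(length(amp))
  # allow the small O(sigma^2/(n*A)) upward bias of the norm estimator
  expect_lt(abs(mean(amp) - 0.5), 3 * se_mc + 0.003)
})
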