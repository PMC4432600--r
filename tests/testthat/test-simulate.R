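test_that("all three generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 10, visits_per_subject = 3,
                    n_features = 20, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_climate("2012-01-01", "2012-03-01", seed = 2),
                   simulate_climate("2012-01-01", "2012-03-01", seed = 2))
  expect_identical(simulate_fbc(50, seed = 3), simulate_fbc(50, seed = 3))
})

test_that("southern hemisphere negates the planted (b, c)", {
  base <- list(n_subjects = 10, visits_per_subject = 2, n_features = 30,
               frac_seasonal = 0.5, acrophase_mode = "mixed", seed = 17)
  north <- simulate_cohort(do.call(sim_config, c(base, hemisphere = "north")))
  south <- simulate_cohort(do.call(sim_config, c(base, hemisphere = "south")))
  expect_equal(south$truth$b, -north$truth$b)
  expect_equal(south$truth$c, -north$truth$c)
  seas <- north$truth$seasonal
  shift <- (north$truth$peak_day[seas] + 182.5) %% 365
  expect_equal(south$truth$peak_day[seas], shift)
})

test_that("simulated cohort has consistent structure and truth records", {
  cfg <- sim_config(n_subjects = 15, visits_per_subject = 4,
                    n_features = 40, frac_seasonal = 0.25,
                    acrophase_mode = "winter", seed = 31)
  st <- simulate_cohort(cfg)
  expect_identical(ncol(st$matrix), nrow(st$samples))
  expect_false(anyNA(st$samples$date_of_bleed))
  expect_true(all(st$samples$date_of_bleed >= cfg$date_range[1] &
                    st$samples$date_of_bleed <= cfg$date_range[2]))
  expect_true(all(st$samples$age_at_bleed >= 18))
  expect_identical(sum(st$truth$seasonal), 10L)
  expect_true(all(st$truth$label[st$truth$seasonal] == "winter"))
  expect_true(all(st$truth$b[!st$truth$seasonal] == 0))
  expect_error(sim_config(date_range = c("2010-01-01", "2009-01-01")),
               "precede")
  expect_error(sim_config(frac_seasonal = 1.5), "frac_seasonal")
  expect_error(sim_config(residual_sd = -1), "non-negative")
})

test_that("non-seasonal feature mean sits within 3 SE of the baseline", {
  cfg <- sim_config(n_subjects = 500, visits_per_subject = 20,
                    n_features = 1, frac_seasonal = 0,
                    covariate_effects = c(age = 0, sex = 0),
                    baseline_mean = 8, seed = 47)
  st <- simulate_cohort(cfg)
  n <- length(st$matrix)
  se <- sqrt(cfg$subject_sd^2 / cfg$n_subjects + cfg$residual_sd^2 / n)
  expect_lt(abs(mean(st$matrix) - 8), 3 * se)
})

test_that("null cohort gives uniform season-test p-values", {
  cfg <- sim_config(n_subjects = 250, visits_per_subject = 1,
                    n_features = 1000, frac_seasonal = 0, subject_sd = 0,
                    covariate_effects = c(age = 0, sex = 0), seed = 53)
  scr <- cosinor_screen(simulate_cohort(cfg), model_spec())
  ks <- suppressWarnings(ks.test(scr$p_season, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("climate series covers the calendar and respects zero noise", {
  cl <- simulate_climate("2011-01-01", "2011-12-31")
  expect_identical(nrow(cl), 365L)
  expect_identical(nrow(simulate_climate("2012-01-01", "2012-12-31")), 366L)
  expect_true(all(cl$sun_hours >= 0))
  cl0 <- simulate_climate("2011-01-01", "2011-12-31",
                          temp_sd = 0, sun_sd = 0)
  yd <- as.POSIXlt(cl0$date)$yday + 1
  expect_equal(cl0$tmean_c, 9 + 9 * cos(2 * pi * (yd - 200) / 365),
               tolerance = 1e-12)
  expect_error(simulate_climate("2011-02-01", "2011-01-01"), "empty")
})

test_that("FBC generator: positive counts, seasonal power, null calibration", {
  tb <- simulate_fbc(400, seed = 61)
  num <- vapply(tb, is.numeric, logical(1))
  resp <- setdiff(names(tb)[num], c("month", "age"))
  expect_true(all(vapply(tb[resp], function(x) all(x > 0), logical(1))))
  expect_error(simulate_fbc(100, seasonal_amplitudes = c(wbc = -0.1)),
               "negative")
  # a strongly seasonal response is flagged at Bonferroni over the panel
  tb2 <- simulate_fbc(1000, seasonal_amplitudes = c(wbc = 0.3, lym = 0,
                                                    plt = 0), seed = 62)
  scr <- fbc_screen(tb2, method = "month_cosinor")
  expect_lt(scr$p_value[scr$response == "wbc"], 0.05 / 3)
  # amplitude zero everywhere: month-cosinor p approximately uniform
  set.seed(63)
  p <- vapply(seq_len(200), function(i) {
    t0 <- simulate_fbc(150, seasonal_amplitudes = c(wbc = 0),
                       seed = 1000 + i)
    month_cosinor(t0, "wbc")$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
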