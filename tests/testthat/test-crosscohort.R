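test_that("BIC fields and preference follow k*ln(n) - 2*logLik", {
  set.seed(81)
  meta <- meta_frame(year_dates(400))
  t <- day_fraction(meta$date_of_bleed)
  y <- 1 + sin(2 * pi * t) + rnorm(400, 0, 0.2)
  f1 <- fit_cosinor(y, meta)
  f0 <- fit_null(y, meta)
  expect_equal(f1$bic, f1$n_params * log(400) - 2 * f1$loglik_ml,
               tolerance = 1e-10)
  expect_true(bic_prefers_seasonal(f1, f0))
  expect_true(bic_prefers_seasonal(10, 12))
  expect_false(bic_prefers_seasonal(12, 10))
})

test_that("under pure noise BIC rarely prefers the seasonal model", {
  cfg <- sim_config(n_subjects = 400, visits_per_subject = 1,
                    n_features = 200, frac_seasonal = 0, subject_sd = 0,
                    covariate_effects = c(age = 0, sex = 0), seed = 83)
  scr <- cosinor_screen(simulate_cohort(cfg), model_spec())
  pref <- mean(scr$bic_s < scr$bic_0)
  expect_lt(pref, 0.05)  # 2-parameter BIC penalty ~ 2*ln(400) ~ 12
})

test_that("candidate gating uses 'significant in at least one' semantics", {
  a <- data.frame(feature_id = c("f1", "f2", "f3"),
                  p_season = c(1e-9, 1, 1))
  b <- data.frame(feature_id = c("f1", "f2", "f3"),
                  p_season = c(1, 1e-9, 1))
  gate <- bonferroni_threshold(0.05, 33297)
  expect_setequal(candidate_features(a, b, gate), c("f1", "f2"))
  a$p_season <- 1; b$p_season <- 1
  expect_length(candidate_features(a, b, gate), 0)
  b$feature_id <- c("g1", "g2", "g3")
  expect_error(candidate_features(a, b, gate), "no feature ids")
})

test_that("fisher_combine: closed forms, monotonicity, null uniformity", {
  expect_equal(fisher_combine(rep(1, 5)), 1)
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0175, tolerance = 2e-3)
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
  expect_error(fisher_combine(c(-0.1)), "0, 1")
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_gt(p0, 0)
  # decreasing any input never increases the output
  set.seed(85)
  for (i in 1:25) {
    p <- runif(4)
    j <- sample(4, 1)
    q <- p; q[j] <- p[j] / 2
    expect_lte(fisher_combine(q), fisher_combine(p))
  }
  # uniform under the global null
  set.seed(86)
  comb <- vapply(seq_len(1000), function(i) fisher_combine(runif(5)),
                 numeric(1))
  expect_gt(suppressWarnings(ks.test(comb, "punif"))$p.value, 0.01)
})

test_that("common_seasonal recovers planted common features", {
  # cohort A plants signal in rows 1..40, cohort B in rows 21..60:
  # only 21..40 are common; 1..20 and 41..60 are cohort-private
  mk <- function(seed, seasonal_rows) {
    cfg <- sim_config(n_subjects = 200, visits_per_subject = 1,
                      n_features = 100, frac_seasonal = 0.4, subject_sd = 0,
                      amplitude_range = c(0.5, 0.8),
                      acrophase_mode = "winter", residual_sd = 0.4,
                      seed = seed)
    st <- simulate_cohort(cfg)
    # generator plants signal in the first 40 rows; rotate to target rows
    perm <- order(c(seasonal_rows, setdiff(1:100, seasonal_rows)))
    st$matrix <- st$matrix[perm, ]
    rownames(st$matrix) <- paste0("f", 1:100)
    st$truth <- st$truth[perm, ]
    st$truth$feature_id <- paste0("f", 1:100)
    st
  }
  a <- mk(91, 1:40)
  b <- mk(92, 21:60)
  scr_a <- cosinor_screen(a, model_spec())
  scr_b <- cosinor_screen(b, model_spec())
  res <- common_seasonal(list(A = scr_a, B = scr_b),
                         plan = list(gate = 1e-6))
  planted <- paste0("f", 21:40)
  sens <- mean(planted %in% res$feature_id)
  spec_ <- mean(!setdiff(paste0("f", 1:100), planted) %in% res$feature_id)
  expect_gte(sens, 0.9)
  expect_gte(spec_, 0.9)
  expect_true(all(res$combined_p[res$feature_id %in% planted] < 1e-6))
  expect_true(all(res$concordant_phase[res$feature_id %in% planted]))
  # invariant to cohort ordering
  res2 <- common_seasonal(list(B = scr_b, A = scr_a),
                          plan = list(gate = 1e-6))
  expect_identical(res$feature_id, res2$feature_id)
  # single cohort degenerates to its own gated BIC-preferred set
  solo <- common_seasonal(list(A = scr_a), plan = list(gate = 1e-6))
  own <- scr_a$feature_id[scr_a$p_season < 1e-6 &
                            scr_a$bic_s < scr_a$bic_0]
  expect_setequal(solo$feature_id, own)
  expect_error(common_seasonal(list()), "empty")
})
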