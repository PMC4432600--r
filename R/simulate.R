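#' Configuration for the synthetic cohort generator
#'
#' Describes a longitudinal expression cohort with the generative structure
#' the cosinor models assume: per-feature annual sinusoids on the log2 scale,
#' additive age and sex effects, a per-subject random intercept and Gaussian
#' residual noise. Defaults give a cohort of roughly the size of the
#' longitudinal PBMC studies this package is aimed at (90 subjects x 5
#' visits = 450 samples).
#'
#' `acrophase_mode` controls where seasonal features peak: `"winter"` draws
#' peak days in mid-December through mid-February, `"summer"` the antiphase
#' window in June-August, `"mixed"` half and half, `"uniform"` anywhere in
#' the year (such features may legitimately be unclassifiable as winter or
#' summer). Southern-hemisphere cohorts have all acrophases shifted by half a
#' year, i.e. `(b, c)` negated.
#'
#' @param n_subjects number of subjects.
#' @param visits_per_subject bleeds per subject; visit dates are drawn
#'   uniformly over `date_range`.
#' @param date_range character/Date vector of length 2, start < end.
#' @param n_features number of features (rows) in the matrix.
#' @param frac_seasonal fraction of features carrying a seasonal signal.
#' @param amplitude_range range (log2 units) from which seasonal amplitudes
#'   `sqrt(b^2 + c^2)` are drawn uniformly.
#' @param acrophase_mode `"uniform"`, `"winter"`, `"summer"` or `"mixed"`.
#' @param subject_sd SD of the per-subject random intercept (log2 units),
#'   drawn independently per feature x subject.
#' @param residual_sd residual SD (log2 units).
#' @param covariate_effects named numeric vector with elements `age` (log2
#'   units per year) and `sex` (log2 shift for males vs females).
#' @param hemisphere `"north"` or `"south"`.
#' @param baseline_mean intercept (log2 units) of every feature.
#' @param seed integer seed; identical configs give byte-identical studies.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 90L, visits_per_subject = 5L,
                       date_range = c("2008-01-01", "2010-12-31"),
                       n_features = 500L, frac_seasonal = 0.2,
                       amplitude_range = c(0.2, 0.8),
                       acrophase_mode = c("uniform", "winter", "summer",
                                          "mixed"),
                       subject_sd = 0.5, residual_sd = 0.5,
                       covariate_effects = c(age = 0.005, sex = 0.1),
                       hemisphere = c("north", "south"),
                       baseline_mean = 8, seed = 1L) {
  acrophase_mode <- match.arg(acrophase_mode)
  hemisphere <- match.arg(hemisphere)
  dr <- as.Date(date_range)
  if (anyNA(dr) || length(dr) != 2L) stop("invalid date_range")
  if (dr[1] >= dr[2]) stop("date_range start must precede end")
  if (n_subjects < 1L || visits_per_subject < 1L || n_features < 1L)
    stop("counts must be positive")
  if (frac_seasonal < 0 || frac_seasonal > 1)
    stop("frac_seasonal must lie in [0, 1]")
  if (subject_sd < 0 || residual_sd < 0) stop("SDs must be non-negative")
  if (length(amplitude_range) != 2L || any(amplitude_range < 0) ||
      amplitude_range[1] > amplitude_range[2])
    stop("amplitude_range must be a non-negative increasing pair")
  ce <- c(age = 0, sex = 0)
  ce[names(covariate_effects)] <- covariate_effects
  structure(list(
    n_subjects = as.integer(n_subjects),
    visits_per_subject = as.integer(visits_per_subject),
    date_range = dr, n_features = as.integer(n_features),
    frac_seasonal = frac_seasonal, amplitude_range = amplitude_range,
    acrophase_mode = acrophase_mode, subject_sd = subject_sd,
    residual_sd = residual_sd, covariate_effects = ce,
    hemisphere = hemisphere, baseline_mean = baseline_mean,
    seed = as.integer(seed)), class = "sim_config")
}

# peak-day windows guaranteeing the planted label survives classification:
# a pure sinusoid peaking on day p is a winter feature iff p is (circularly)
# within ~(-30, 60); we stay well inside.
.draw_peak_days <- function(n, mode) {
  winter <- function(k) (runif(k, -15, 45)) %% 365
  summer <- function(k) runif(k, 167.5, 227.5)
  switch(mode,
         winter = winter(n),
         summer = summer(n),
         uniform = runif(n, 0, 365),
         mixed = {
           p <- numeric(n)
           half <- seq_len(n) <= ceiling(n / 2)
           p[half] <- winter(sum(half))
           p[!half] <- summer(sum(!half))
           p
         })
}

#' Simulate a longitudinal expression cohort with known seasonal truth
#'
#' Generates a feature-by-sample log2 expression matrix according to the
#' additive model `baseline + b*sin(2*pi*t) + c*cos(2*pi*t) + beta_age*age +
#' beta_sex*male + u_subject + noise`, with `(b, c)` determined by a
#' uniformly drawn amplitude and a peak day drawn per `acrophase_mode`, and
#' `u_subject ~ N(0, subject_sd^2)` drawn once per feature x subject (each
#' feature's model has its own subject intercepts, matching the per-feature
#' mixed models fitted downstream). Southern-hemisphere cohorts negate
#' `(b, c)`, i.e. shift every acrophase by half a year.
#'
#' @param config a [sim_config()].
#' @return an `expression_study`: list with `matrix` (features x samples,
#'   log2), `samples` (metadata data frame with `sample_id`, `subject_id`,
#'   `family_id`, `date_of_bleed`, `age_at_bleed`, `sex`, `cohort`), `truth`
#'   (per-feature `seasonal`, `b`, `c`, `amplitude`, `peak_day`, `label`)
#'   and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  nv <- config$visits_per_subject
  n <- ns * nv
  m <- config$n_features

  subj <- sprintf("S%04d", seq_len(ns))
  sex_s <- ifelse(rbinom(ns, 1L, 0.5) == 1L, "M", "F")
  age0 <- runif(ns, 18, 70)

  span <- as.integer(config$date_range[2] - config$date_range[1])
  offs <- sample.int(span + 1L, n, replace = TRUE) - 1L
  dates <- config$date_range[1] + offs
  subject_idx <- rep(seq_len(ns), each = nv)
  # order each subject's visits chronologically
  ord <- order(subject_idx, dates)
  dates <- dates[ord]
  age <- age0[subject_idx] + as.numeric(dates - config$date_range[1]) / 365.25

  samples <- data.frame(
    sample_id = sprintf("smp%05d", seq_len(n)),
    subject_id = subj[subject_idx],
    family_id = subj[subject_idx],
    date_of_bleed = dates,
    age_at_bleed = age,
    sex = sex_s[subject_idx],
    cohort = "sim",
    stringsAsFactors = FALSE)

  n_seasonal <- round(config$frac_seasonal * m)
  amp <- b <- cc <- peak <- numeric(m)
  seasonal <- seq_len(m) <= n_seasonal
  if (n_seasonal > 0) {
    amp[seasonal] <- runif(n_seasonal, config$amplitude_range[1],
                           config$amplitude_range[2])
    peak[seasonal] <- .draw_peak_days(n_seasonal, config$acrophase_mode)
    b[seasonal] <- amp[seasonal] * sin(2 * pi * peak[seasonal] / 365)
    cc[seasonal] <- amp[seasonal] * cos(2 * pi * peak[seasonal] / 365)
  }
  if (config$hemisphere == "south") {
    b <- -b
    cc <- -cc
    peak <- ifelse(seasonal, (peak + 182.5) %% 365, 0)
  }

  t <- day_fraction(samples$date_of_bleed)
  ce <- config$covariate_effects
  fixed_part <- config$baseline_mean +
    ce[["age"]] * samples$age_at_bleed +
    ce[["sex"]] * (samples$sex == "M")
  U <- matrix(rnorm(m * ns, 0, config$subject_sd), m, ns)
  E <- outer(b, sin(2 * pi * t)) + outer(cc, cos(2 * pi * t)) +
    matrix(fixed_part, m, n, byrow = TRUE) +
    U[, subject_idx, drop = FALSE] +
    matrix(rnorm(m * n, 0, config$residual_sd), m, n)
  dimnames(E) <- list(sprintf("feat%05d", seq_len(m)), samples$sample_id)

  truth <- data.frame(
    feature_id = rownames(E), seasonal = seasonal,
    b = b, c = cc, amplitude = amp,
    peak_day = peak,
    label = vapply(seq_len(m), function(j) {
      if (!seasonal[j]) "not_seasonal" else classify_season(c(b[j], cc[j]))
    }, character(1)),
    stringsAsFactors = FALSE)

  structure(list(matrix = E, samples = samples, truth = truth,
                 config = config),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d features x %d samples (%d subjects)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$samples$subject_id))))
  cat(sprintf("  dates %s .. %s\n", min(x$samples$date_of_bleed),
              max(x$samples$date_of_bleed)))
  if (!is.null(x$truth))
    cat(sprintf("  simulated; %d seasonal features planted\n",
                sum(x$truth$seasonal)))
  invisible(x)
}

#' Simulate a daily climate series
#'
#' Daily mean temperature and sunlight hours over a date range: each is an
#' annual sinusoid (temperate-latitude defaults: temperature peaking in late
#' July, day length at the June solstice) plus AR(1) noise; sunlight is
#' truncated at zero. With the noise SDs set to zero the series is exactly
#' sinusoidal.
#'
#' @param start,end first and last day (inclusive).
#' @param seed integer seed.
#' @param temp_mean,temp_amplitude,temp_peak_day annual temperature cycle
#'   (degrees C; peak day-of-year).
#' @param temp_sd marginal SD of the AR(1) temperature noise.
#' @param sun_mean,sun_amplitude,sun_peak_day annual sunlight cycle (hours).
#' @param sun_sd marginal SD of the AR(1) sunlight noise.
#' @param ar AR(1) coefficient shared by both noise processes.
#' @return a `climate_series` data frame: `date`, `tmean_c`, `sun_hours`.
#' @export
simulate_climate <- function(start, end, seed = 1L,
                             temp_mean = 9, temp_amplitude = 9,
                             temp_peak_day = 200, temp_sd = 3,
                             sun_mean = 5.5, sun_amplitude = 3.5,
                             sun_peak_day = 172, sun_sd = 2,
                             ar = 0.6) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) stop("empty date range")
  set.seed(as.integer(seed))
  dates <- seq(start, end, by = "day")
  nd <- length(dates)
  lt <- as.POSIXlt(dates)
  yd <- lt$yday + 1L
  ndays <- .days_in_year(lt$year + 1900L)
  ar1 <- function(sd) {
    if (sd == 0) return(rep(0, nd))
    e <- rnorm(nd, 0, sd * sqrt(1 - ar^2))
    as.numeric(stats::filter(e, ar, method = "recursive"))
  }
  tm <- temp_mean +
    temp_amplitude * cos(2 * pi * (yd - temp_peak_day) / ndays) + ar1(temp_sd)
  su <- sun_mean +
    sun_amplitude * cos(2 * pi * (yd - sun_peak_day) / ndays) + ar1(sun_sd)
  out <- data.frame(date = dates, tmean_c = tm, sun_hours = pmax(su, 0))
  class(out) <- c("climate_series", "data.frame")
  out
}

#' Simulate a full blood count table with seasonal log-means
#'
#' One row per donor, each bled once on a uniformly drawn date: haematology
#' responses are log-normal around typical adult reference means, with the
#' log-mean carrying a first-harmonic annual cycle of the specified amplitude
#' (peaking in mid-January by default, mirroring winter-high immune cell
#' counts), a mild age trend and sex shift, so all counts are strictly
#' positive by construction.
#'
#' @param n_donors number of donors (> 0).
#' @param seasonal_amplitudes named non-negative vector of log-scale seasonal
#'   amplitudes, one per response column to generate. The default panel is
#'   `wbc, lym, neu, mon, eos, bas, plt, mcv, mch` with small amplitudes.
#' @param seed integer seed.
#' @param year calendar year over which bleed dates are drawn.
#' @param peak_day day-of-year at which the seasonal log-mean peaks.
#' @param residual_sd log-scale residual SD (common to all responses).
#' @return an `fbc_table` data frame: `donor_id`, `date`, `month`, `age`,
#'   `sex`, plus one numeric column per response. The amplitude vector is
#'   attached as attribute `"seasonal_amplitudes"`.
#' @export
simulate_fbc <- function(n_donors = 1000L,
                         seasonal_amplitudes = c(wbc = 0.05, lym = 0.05,
                                                 neu = 0.06, mon = 0.08,
                                                 eos = 0.03, bas = 0.03,
                                                 plt = 0.04, mcv = 0.003,
                                                 mch = 0.003),
                         seed = 1L, year = 2013L, peak_day = 15,
                         residual_sd = 0.12) {
  if (n_donors <= 0) stop("n_donors must be positive")
  if (is.null(names(seasonal_amplitudes)) ||
      any(!nzchar(names(seasonal_amplitudes))))
    stop("seasonal_amplitudes must be a named vector")
  if (any(seasonal_amplitudes < 0)) stop("negative amplitudes not allowed")
  set.seed(as.integer(seed))
  baselines <- c(wbc = 6.5, lym = 1.9, neu = 3.8, mon = 0.5, eos = 0.15,
                 bas = 0.05, plt = 250, mcv = 90, mch = 30)
  start <- as.Date(sprintf("%d-01-01", year))
  nd <- .days_in_year(year)
  dates <- start + (sample.int(nd, n_donors, replace = TRUE) - 1L)
  yd <- as.POSIXlt(dates)$yday + 1L
  age <- runif(n_donors, 18, 75)
  sex <- ifelse(rbinom(n_donors, 1L, 0.5) == 1L, "M", "F")
  out <- data.frame(
    donor_id = sprintf("D%05d", seq_len(n_donors)),
    date = dates, month = as.POSIXlt(dates)$mon + 1L,
    age = age, sex = sex, stringsAsFactors = FALSE)
  for (resp in names(seasonal_amplitudes)) {
    base <- if (resp %in% names(baselines)) baselines[[resp]] else 1
    lmu <- log(base) +
      seasonal_amplitudes[[resp]] * cos(2 * pi * (yd - peak_day) / nd) +
      0.001 * (age - 45) + 0.02 * (sex == "M")
    out[[resp]] <- exp(lmu + rnorm(n_donors, 0, residual_sd))
  }
  attr(out, "seasonal_amplitudes") <- seasonal_amplitudes
  class(out) <- c("fbc_table", "data.frame")
  out
}
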