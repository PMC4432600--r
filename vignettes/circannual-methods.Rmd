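---
title: "Methods: cosinor models for circannual rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosinor models for circannual rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `circannual`, the
choices that were genuinely open when the package was designed, and what the
synthetic-data tests do and do not establish.

## The cosinor model and its season test

A rhythm with a fixed one-year period is linear in `sin(2*pi*t)` and
`cos(2*pi*t)` once time is expressed as the fraction of the year elapsed,
`t = day-of-year / days-in-year` (`day_fraction()`; leap years use 366 as
the denominator). For each feature we fit

    y = a + b*sin(2*pi*t) + c*cos(2*pi*t) + covariates + u + e

and compare it against the same model without the sine/cosine pair. The
amplitude of the fitted rhythm is `sqrt(b^2 + c^2)` (half the peak-to-trough
range) and the acrophase is `atan2(b, c)/(2*pi)` years, i.e. a pure positive
cosine (`b = 0, c > 0`) peaks at new year and a pure sine (`b > 0, c = 0`)
at the spring equinox.

Assumptions: the response is approximately Gaussian on the modelling scale
(log2 for expression; `transform = "log"` is available for right-skewed
analytes), the rhythm is a single first harmonic, covariate effects are
linear and shared across seasons, and repeated measures are exchangeable
within subject given a subject-level intercept.

**ML, not REML.** Random-intercept models are fitted by maximum likelihood
(`lme4::lmer(..., REML = FALSE)`). REML likelihoods are not comparable
between models that differ in fixed effects, and both the season comparison
and BIC compare exactly such models, so ML is the only coherent choice. The
cost — slightly downward-biased variance components — does not affect the
quantities we report.

**Test family.** Without random intercepts the comparison is the exact
F-test, `F = ((RSS0 - RSS1)/2) / (RSS1/(n - p))` on `(2, n - p)` df. With
random intercepts the reference distribution of the ANOVA-style comparison
is not exact in finite samples; we use the likelihood-ratio statistic
`2*(ll1 - ll0)` against chi-square with 2 df, which the type-I-error
acceptance test shows to be well calibrated at the cohort sizes of interest
(~450 samples, 90 subjects). Both fits being ML makes the LRT valid; an
F-approximation is deliberately not offered for the mixed path to avoid a
silently wrong denominator df.

**BIC.** `BIC = k*ln(n) - 2*logLik` with `n` the total number of
observations and `k` counting fixed effects, variance components and the
residual variance. Using total observations (rather than the number of
subjects) is the conventional, reproducible choice; nothing downstream is
sensitive to it because both compared models share the same `n`.

## Classification and fold change

A Bonferroni-significant feature (threshold `alpha/m`; optionally also a
mean log2 expression >= 6 gate, applied only where a cohort's analysis
calls for it) is labelled from the sign pattern of its seasonal component
`r(t) = b*sin(2*pi*t) + c*cos(2*pi*t)` on a fixed 365-day calendar:
*winter* requires `r > 0` on every day of December, January and February
(days 335-365 and 1-59) and `r < 0` on every day of June, July and August
(days 152-243); *summer* is the mirror image; anything else — notably a
pure sine, which changes sign inside both windows — is *unclassified*.
Every calendar day of both windows is evaluated (a coarser grid could
misclassify near-boundary acrophases), and the inequalities are strict: a
fitted zero on any window day yields *unclassified*. Fold change is
`2^|r(15/365) - r(196/365)|`, the 15 January vs 15 July contrast, and is
>= 1 by construction.

## Cross-cohort concordance

Within a cohort group, candidate features must pass the Bonferroni gate in
at least one member cohort (union semantics); a candidate is retained only
if BIC prefers the seasonal model in *every* member cohort; group lists are
intersected. The gate denominator is configurable (default `0.05/33297`,
the probeset count of the platform the in-house analyses used; an
alternative platform with 22,283 probesets would use that count instead).
Evidence is pooled with Fisher's method, `-2*sum(ln p)` against
chi-square with `2k` df; p-values of exactly zero (upstream underflow) are
clamped to the smallest positive double with a warning, since the statistic
is undefined at zero. Phase concordance compares the signs of the fitted
cosine coefficients after negating southern-hemisphere cohorts, whose
annual cycle is half a year out of phase; the raw per-cohort signs are also
reported so an inverted cohort is visible as such.

## Blood-count models

When only the bleed month is known, the cosinor runs on `t = month/12`
(mapping configurable; `(month - 0.5)/12` would centre each month but the
F-test is invariant to such a rotation, so the simpler convention is used)
with no covariates and an F-test on `(2, n - 3)` df. With dates, age and
sex available, the seasonal signal is modelled with three Fourier harmonic
pairs (six columns) alongside sex and a natural cubic spline in age with 4
df (3 interior knots at age quantiles — enough curvature for adult age
trends without overfitting; configurable, as the original choice of df is
not recoverable). Season is the F-test of the six harmonic columns against
the covariate-only model. At `k = 1`, month time and no covariates this
reduces exactly to the month cosinor, which the tests assert.

## Sex inference and infection tests

Sex calls use the first principal component of four Y-expressed genes
(DDX3Y, KDM5D, USP9Y, RPS4Y1) across samples, on centred *unscaled* values:
the four markers share units and near-binary dynamic range, so covariance
PCA is the natural reading of an unstated scaling choice. A principal
component's sign is arbitrary, so PC1 is oriented to increase with mean
marker expression before thresholding at zero (score > 0 is male, < 0
female, exactly 0 uncallable). The infection-effect test summarises a
supplied feature set (e.g. a cohort's seasonal genes, or any co-expression
module subset) as PC1 and runs one-way ANOVA of the scores on the
infection grouping; with two groups this is identically the pooled t-test
with F = t².

## The synthetic cohort generator

`simulate_cohort()` generates exactly the world the models assume: log2
expression that is additive in a baseline, a first-harmonic annual signal,
linear age and sex effects, a Gaussian per-subject intercept and Gaussian
residual noise. Choices that the generator fixes, with rationale:

* **Sizes.** 90 subjects x 5 visits = 450 samples by default, the scale of
  the longitudinal PBMC cohorts this methodology targets.
* **Visit dates** are uniform over the date range — cohort visit calendars
  are irregular in practice and uniform is the neutral stand-in; monthly
  accrual patterns are deliberately not emulated.
* **Variances.** Neither residual nor between-subject variance magnitudes
  are dictated by the method, so both default to 0.5 (log2 units): a
  realistic regime where repeated-measures correlation matters
  (intra-class correlation 0.5) and an amplitude-0.3 rhythm is detectable
  but not trivial at n = 450. These are configuration, not claims.
* **Random intercepts** are drawn once per (feature, subject) — constant
  across a subject's visits, independent across features — mirroring the
  per-feature mixed models fitted downstream.
* **Acrophases.** Winter-mode peak days are drawn in mid-December through
  mid-February and summer-mode in the antiphase window, comfortably inside
  the region where a pure sinusoid satisfies the strict sign-window
  classification, so planted labels are well defined; `"uniform"` mode
  produces legitimately unclassifiable features. Southern-hemisphere
  cohorts negate `(b, c)`, i.e. shift every acrophase by 182.5 days.
* **Covariates.** Ages uniform 18-70 at entry and incremented with the
  calendar; sex Bernoulli(0.5); small default effects (0.005 log2/year,
  0.1 log2 M vs F) so adjustment is exercised without dominating.

The climate generator is an annual sinusoid plus AR(1) noise (temperate
defaults; zero-noise mode is exactly sinusoidal for closed-form tests); the
FBC generator draws log-normal counts around adult reference means with a
first-harmonic seasonal log-mean peaking in mid-January, so counts are
strictly positive.

What a green test does **not** establish: performance under microarray
normalisation artefacts, batch effects, non-sinusoidal or multi-harmonic
seasonality, missing-at-random visit structure, or heavy-tailed noise —
none of which the generator emulates. The acceptance suite shows the
machinery is correct and calibrated in the stated world, not that any
particular biological cohort will yield any particular gene count.

## Numerical conventions

* p-values that underflow are clamped to `.Machine$double.xmin`, never 0.
* A seasonal log-likelihood below the null's by more than `1e-6` (relative)
  signals optimizer failure: an error for single fits, a
  `converged = FALSE` row in the matrix screen; such features are excluded
  from selection and summaries, never imputed.
* Rank-deficient designs error with the aliased columns named; constant
  exposures and constant ages (degenerate spline) error likewise.
* The weekly climate exposure is the mean over the 7 days strictly before
  the bleed (`[date-7, date-1]`), excluding the bleed day itself; missing
  days are an error, not an interpolation.
* The matrix screen shares one design across features: a single QR pass for
  OLS, `lme4::refit()` on template models for the mixed path (~30 ms per
  feature at n = 450), which is what keeps the 2,000-feature calibration
  test inside a couple of minutes.

## Known limitations

Only the one-year period is supported (no free-period rhythmometry, no
harmonics beyond the blood-count Fourier model); confidence intervals for
amplitude and acrophase are not provided; the cross-cohort step is a
fixed-effect intersection rule, not a random-effects meta-analysis; and the
mixed-model season test relies on the asymptotic chi-square(2) reference,
which is anti-conservative for very small cohorts (tens of samples) — the
calibration evidence covers the hundreds-of-samples regime.
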