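#' Winter and summer day windows on a 365-day calendar
#'
#' The classification windows: winter is every day of December, January and
#' February (90 days; February has 28 days on the fixed 365-day calendar used
#' throughout classification), summer is every day of June, July and August
#' (92 days).
#'
#' @return list with integer day-of-year vectors `winter_days` (1-59,
#'   335-365) and `summer_days` (152-243).
#' @export
season_windows <- function() {
  list(winter_days = c(1:59, 335:365), summer_days = 152:243)
}

# seasonal component at year-fraction t for coefficients (b, c)
.rel_expr <- function(b, c, t) b * sin(2 * pi * t) + c * cos(2 * pi * t)

.coef_pair <- function(fit) {
  if (inherits(fit, "cosinor_fit")) c(fit$b_hat, fit$c_hat)
  else if (is.numeric(fit) && length(fit) == 2L) as.numeric(fit)
  else stop("expected a cosinor_fit or a numeric (b, c) pair")
}

#' Relative estimated log2 expression at a time of year
#'
#' Evaluates the fitted seasonal component `r(t) = b_hat * sin(2*pi*t) +
#' c_hat * cos(2*pi*t)` — the seasonal deviation from the subject's baseline,
#' excluding intercept and covariates.
#'
#' @param fit a `cosinor_fit`, or a numeric vector `c(b, c)`.
#' @param t year fraction(s) in (0, 1] (see [day_fraction()]).
#' @return numeric vector `r(t)` in the response units (log2 for expression).
#' @export
relative_expression <- function(fit, t) {
  bc <- .coef_pair(fit)
  if (!all(is.finite(bc))) stop("non-finite seasonal coefficients")
  .rel_expr(bc[1], bc[2], t)
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 33297)  # ~1.52e-06, genome-wide level for
#'                                    # a 33,297-probeset array
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be a positive count")
  alpha / m
}

#' Classify a seasonal fit as winter- or summer-expressed
#'
#' A feature is a *winter* feature if its relative expression `r(t)` is
#' strictly positive on every day of December, January and February and
#' strictly negative on every day of June, July and August; a *summer*
#' feature if the reverse holds; otherwise it is *unclassified* (e.g. a pure
#' sine, which peaks at the equinox and changes sign inside both windows).
#' Days are evaluated on the fixed 365-day calendar, every day of both
#' windows; a fitted value of exactly zero on any window day fails the strict
#' inequality and yields `"unclassified"`.
#'
#' @inheritParams relative_expression
#' @param windows day windows, by default [season_windows()].
#' @return one of `"winter"`, `"summer"`, `"unclassified"`.
#' @export
classify_season <- function(fit, windows = season_windows()) {
  bc <- .coef_pair(fit)
  if (!all(is.finite(bc))) return("unclassified")
  rw <- .rel_expr(bc[1], bc[2], windows$winter_days / 365)
  rs <- .rel_expr(bc[1], bc[2], windows$summer_days / 365)
  if (all(rw > 0) && all(rs < 0)) "winter"
  else if (all(rw < 0) && all(rs > 0)) "summer"
  else "unclassified"
}

#' Winter/summer fold change of a seasonal fit
#'
#' Two raised to the absolute difference of the relative estimated log2
#' expression between 15 January and 15 July (days 15 and 196 of a 365-day
#' calendar year): `2^|r(15/365) - r(196/365)| >= 1`.
#'
#' @inheritParams relative_expression
#' @return fold change, `>= 1`.
#' @export
fold_change <- function(fit) {
  bc <- .coef_pair(fit)
  r15 <- .rel_expr(bc[1], bc[2], 15 / 365)
  r196 <- .rel_expr(bc[1], bc[2], 196 / 365)
  2^abs(r15 - r196)
}

#' Select and label seasonal features from a screen
#'
#' Applies the significance gates to a [cosinor_screen()] result — a
#' Bonferroni-corrected p-value threshold and, optionally, a minimum mean
#' expression (the log2 >= 6 filter used for in-house PBMC cohorts; omit it
#' for cohorts where it was not applied) — then labels every gated feature
#' winter/summer/unclassified via [classify_season()] and computes its
#' [fold_change()]. Non-converged features never pass the gates.
#'
#' @param results data frame from [cosinor_screen()].
#' @param threshold p-value threshold, typically
#'   [bonferroni_threshold()]`(alpha, m)`.
#' @param mean_expr_min optional minimum mean expression (log2 units);
#'   `NULL` disables the filter.
#' @return data frame of `SeasonalGeneRecord`s: `feature_id`, `p_season`,
#'   `passes_bonferroni`, `mean_expr`, `passes_expression_filter`, `label`
#'   (`"not_seasonal"` for features failing either gate), `fold_change`.
#'   An attribute `"counts"` carries the per-label tally of selected
#'   features.
#' @export
select_seasonal <- function(results, threshold, mean_expr_min = NULL) {
  stopifnot(is.data.frame(results),
            all(c("feature_id", "p_season", "mean_expr", "b_hat", "c_hat")
                %in% names(results)))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  conv <- if ("converged" %in% names(results)) results$converged
          else rep(TRUE, nrow(results))
  pass_p <- conv & !is.na(results$p_season) & results$p_season < threshold
  pass_e <- if (is.null(mean_expr_min)) rep(TRUE, nrow(results))
            else results$mean_expr >= mean_expr_min
  selected <- pass_p & pass_e
  label <- rep("not_seasonal", nrow(results))
  fc <- rep(NA_real_, nrow(results))
  for (i in which(selected)) {
    bc <- c(results$b_hat[i], results$c_hat[i])
    label[i] <- classify_season(bc)
    fc[i] <- fold_change(bc)
  }
  out <- data.frame(
    feature_id = results$feature_id,
    p_season = results$p_season,
    passes_bonferroni = pass_p,
    mean_expr = results$mean_expr,
    passes_expression_filter = pass_e,
    label = label,
    fold_change = fc,
    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(
    winter = sum(label == "winter"),
    summer = sum(label == "summer"),
    unclassified = sum(label == "unclassified"),
    not_seasonal = sum(label == "not_seasonal"))
  out
}
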