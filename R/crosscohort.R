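#' Does BIC prefer the seasonal model?
#'
#' @param fit_seasonal,fit_null either two `cosinor_fit` objects fitted by ML
#'   on the same data, or two numeric BIC values.
#' @return `TRUE` iff the seasonal model's BIC is strictly smaller.
#' @export
bic_prefers_seasonal <- function(fit_seasonal, fit_null) {
  bic <- function(x) {
    if (inherits(x, "cosinor_fit")) x$bic
    else if (is.numeric(x) && length(x) == 1L) x
    else stop("expected a cosinor_fit or a single BIC value")
  }
  b1 <- bic(fit_seasonal)
  b0 <- bic(fit_null)
  if (inherits(fit_seasonal, "cosinor_fit") &&
      inherits(fit_null, "cosinor_fit") &&
      fit_seasonal$n_obs != fit_null$n_obs)
    stop("fits are not on the same data")
  if (!is.finite(b1) || !is.finite(b0)) stop("non-finite BIC")
  b1 < b0
}

#' Candidate features for a cohort pair
#'
#' The union gate: features whose season-test p-value falls below `gate` in
#' *at least one* of the two cohorts.
#'
#' @param result_a,result_b [cosinor_screen()] data frames sharing a feature
#'   namespace.
#' @param gate p-value threshold, e.g.
#'   `bonferroni_threshold(0.05, 33297)`.
#' @return character vector of candidate feature ids.
#' @export
candidate_features <- function(result_a, result_b, gate) {
  shared <- intersect(result_a$feature_id, result_b$feature_id)
  if (length(shared) == 0L) stop("cohorts share no feature ids")
  pa <- result_a$p_season[match(shared, result_a$feature_id)]
  pb <- result_b$p_season[match(shared, result_b$feature_id)]
  hit <- (!is.na(pa) & pa < gate) | (!is.na(pb) & pb < gate)
  shared[hit]
}

#' Combine p-values with Fisher's product method
#'
#' `X = -2 * sum(log(p))` referred to the upper tail of a chi-square
#' distribution with `2 * length(p)` degrees of freedom. Zero p-values
#' (numerical underflow upstream) are clamped to the smallest positive
#' double with a warning, since the statistic is undefined at zero.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values supplied")
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (any(p_values == 0)) {
    warning("p-value(s) of exactly 0 clamped to smallest positive double")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  x <- -2 * sum(log(p_values))
  pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Identify features seasonal across multiple cohorts
#'
#' Implements the two-stage concordance procedure: within each cohort group
#' of the pairing `plan`, features significant below `gate` in at least one
#' member cohort are candidates, and a candidate survives the group if the
#' seasonal model's BIC beats the null's in *every* member cohort. The final
#' report is the intersection of the group lists. Evidence is then pooled
#' per feature across all cohorts with [fisher_combine()], and phase
#' concordance is recorded from the signs of the cosine coefficients after
#' flipping southern-hemisphere cohorts (whose annual cycle is half a year
#' out of phase with the north).
#'
#' @param cohort_results named list of [cosinor_screen()] data frames.
#' @param plan list with `groups` (list of character vectors of cohort
#'   names; default: all cohorts in one group) and `gate` (candidate
#'   p-value threshold; default `bonferroni_threshold(0.05, 33297)`).
#' @param hemispheres named character vector (`"north"`/`"south"`) per
#'   cohort; unnamed cohorts default to north.
#' @return data frame with one row per common seasonal feature:
#'   `feature_id`, one `bic_delta_<cohort>` column per cohort (seasonal
#'   minus null BIC; negative favours seasonality), one `sign_<cohort>`
#'   column (raw sign of the fitted cosine coefficient), `combined_p`, and
#'   `concordant_phase` (`TRUE` iff hemisphere-adjusted cosine signs agree
#'   across all cohorts).
#' @export
common_seasonal <- function(cohort_results, plan = NULL, hemispheres = NULL) {
  if (!is.list(cohort_results) || length(cohort_results) == 0L)
    stop("empty cohort list")
  if (is.null(names(cohort_results)) || any(!nzchar(names(cohort_results))))
    names(cohort_results) <- paste0("cohort", seq_along(cohort_results))
  cohorts <- names(cohort_results)
  if (is.null(plan)) plan <- list()
  if (is.null(plan$groups)) plan$groups <- list(cohorts)
  if (is.null(plan$gate)) plan$gate <- bonferroni_threshold(0.05, 33297)
  hemi <- setNames(rep("north", length(cohorts)), cohorts)
  if (!is.null(hemispheres)) hemi[names(hemispheres)] <- hemispheres

  bic_pref <- function(res, ids) {
    d <- res$bic_s[match(ids, res$feature_id)] -
      res$bic_0[match(ids, res$feature_id)]
    !is.na(d) & d < 0
  }

  group_list <- lapply(plan$groups, function(g) {
    stopifnot(all(g %in% cohorts))
    # candidates: gate passed in >= 1 cohort of the group
    shared <- Reduce(intersect, lapply(cohort_results[g],
                                       function(r) r$feature_id))
    if (length(shared) == 0L) stop("cohorts share no feature ids")
    hit <- Reduce(`|`, lapply(cohort_results[g], function(r) {
      p <- r$p_season[match(shared, r$feature_id)]
      !is.na(p) & p < plan$gate
    }))
    cand <- shared[hit]
    # keep those BIC-preferred in every cohort of the group
    keep <- Reduce(`&`, lapply(cohort_results[g], bic_pref, ids = cand))
    cand[keep]
  })
  common <- sort(Reduce(intersect, group_list))

  out <- data.frame(feature_id = common, stringsAsFactors = FALSE)
  signs <- matrix(NA_real_, length(common), length(cohorts),
                  dimnames = list(common, cohorts))
  for (co in cohorts) {
    r <- cohort_results[[co]]
    idx <- match(common, r$feature_id)
    out[[paste0("bic_delta_", co)]] <- r$bic_s[idx] - r$bic_0[idx]
    out[[paste0("sign_", co)]] <- sign(r$c_hat[idx])
    signs[, co] <- sign(r$c_hat[idx]) *
      if (hemi[[co]] == "south") -1 else 1
  }
  out$combined_p <- vapply(common, function(f) {
    ps <- vapply(cohort_results, function(r) {
      p <- r$p_season[match(f, r$feature_id)]
      if (is.na(p)) 1 else p
    }, numeric(1))
    fisher_combine(ps)
  }, numeric(1))
  out$concordant_phase <- apply(signs, 1L, function(s) {
    s <- s[!is.na(s) & s != 0]
    length(s) > 0L && length(unique(s)) == 1L
  })
  rownames(out) <- NULL
  out
}
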