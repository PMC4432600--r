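#' Specify the fixed and random structure of a seasonality model
#'
#' A `model_spec` describes everything about a per-feature model except the
#' seasonal terms themselves: which fixed covariates to adjust for, which
#' grouping factors receive random intercepts, and how the response is
#' transformed before fitting. Cohort-specific conventions (e.g. age + sex
#' fixed effects with a per-subject random intercept for a longitudinal PBMC
#' cohort, or family + zygosity random intercepts for a twin study) are all
#' expressed through this one object.
#'
#' Covariate names are resolved against the sample metadata with the aliases
#' `age -> age_at_bleed`, `sex -> sex`, `subject -> subject_id`,
#' `family -> family_id`, `zygosity -> zygosity`; any other name must match a
#' metadata column directly. Interactions are written `"age:sex"`.
#'
#' @param fixed character vector of fixed-effect covariate names
#'   (possibly including interactions such as `"age:sex"`).
#' @param random character vector of grouping keys that receive random
#'   intercepts (e.g. `"subject"`, `"family"`). Empty means ordinary least
#'   squares.
#' @param transform response transform applied before fitting:
#'   `"identity"` (default), `"log"` or `"log2"`.
#' @return an object of class `model_spec`.
#' @examples
#' model_spec(fixed = c("age", "sex"), random = "subject")
#' @export
model_spec <- function(fixed = character(), random = character(),
                       transform = c("identity", "log", "log2")) {
  transform <- match.arg(transform)
  stopifnot(is.character(fixed), is.character(random))
  structure(list(fixed = fixed, random = random, transform = transform),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec\n")
  cat("  fixed:    ", if (length(x$fixed)) paste(x$fixed, collapse = " + ")
      else "(intercept only)", "\n")
  cat("  random:   ", if (length(x$random)) paste(x$random, collapse = ", ")
      else "(none; OLS)", "\n")
  cat("  transform:", x$transform, "\n")
  invisible(x)
}

# metadata aliases: spec-level names -> canonical metadata columns
.meta_alias <- c(age = "age_at_bleed", sex = "sex", subject = "subject_id",
                 family = "family_id", zygosity = "zygosity")

.resolve_column <- function(name, meta, what = "covariate") {
  col <- if (name %in% names(.meta_alias)) .meta_alias[[name]] else name
  if (!col %in% names(meta)) {
    stop(what, " '", name, "' not found in sample metadata (looked for column '",
         col, "')")
  }
  v <- meta[[col]]
  if (anyNA(v)) stop(what, " '", name, "' has missing values")
  v
}

.apply_transform <- function(y, transform) {
  switch(transform,
         identity = y,
         log = {
           if (any(y <= 0)) stop("log transform requires a positive response")
           log(y)
         },
         log2 = {
           if (any(y <= 0)) stop("log2 transform requires a positive response")
           log2(y)
         })
}

# Assemble the model frame shared by all fitting paths. Seasonal terms are
# sin/cos of the year fraction; an exposure column replaces them for the
# climate-predictor models.
.build_model_frame <- function(y, meta, spec, seasonal = TRUE,
                               exposure = NULL) {
  dat <- data.frame(y = y)
  rhs <- character()
  if (seasonal) {
    t <- day_fraction(meta$date_of_bleed)
    dat$sin_t <- sin(2 * pi * t)
    dat$cos_t <- cos(2 * pi * t)
    rhs <- c("sin_t", "cos_t")
  }
  if (!is.null(exposure)) {
    stopifnot(length(exposure) == nrow(meta))
    if (anyNA(exposure)) stop("missing exposure values")
    if (sd(exposure) == 0) stop("exposure is constant: rank-deficient design")
    dat$exposure <- exposure
    rhs <- c(rhs, "exposure")
  }
  for (term in spec$fixed) {
    parts <- strsplit(term, "[:*]")[[1]]
    for (p in parts) {
      if (!p %in% names(dat)) {
        v <- .resolve_column(p, meta)
        dat[[p]] <- if (is.character(v)) factor(v) else v
      }
    }
    rhs <- c(rhs, gsub("\\*", ":", term))
  }
  rand <- character()
  for (g in spec$random) {
    v <- .resolve_column(g, meta, what = "grouping key")
    gname <- paste0(".g_", g)
    dat[[gname]] <- factor(v)
    rand <- c(rand, gname)
  }
  list(dat = dat, rhs = rhs, rand = rand)
}
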