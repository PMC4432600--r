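#' Per-feature seasonality screen across an expression matrix
#'
#' Runs the cosinor / null model comparison of [fit_cosinor()],
#' [fit_null()] and [season_test()] for every row of an expression study's
#' matrix, sharing the design across features for speed. With no random
#' intercepts all features are solved in one QR pass (the design is common,
#' only the response changes); with random intercepts the mixed model is
#' fitted once per model as a template and re-fitted per feature via
#' [lme4::refit()].
#'
#' Features whose mixed-model optimisation fails are reported with
#' `converged = FALSE` and `NA` statistics rather than silently dropped or
#' imputed; downstream selection ignores them.
#'
#' @param study an `expression_study` (see [simulate_cohort()] /
#'   [read_expression_study()]), or a plain feature-by-sample matrix if
#'   `meta` is given.
#' @param spec a [model_spec()].
#' @param meta sample metadata data frame, required when `study` is a bare
#'   matrix.
#' @return a data frame with one row per feature and columns `feature_id`,
#'   `b_hat`, `c_hat`, `loglik_s`, `loglik_0`, `bic_s`, `bic_0`,
#'   `statistic`, `df`, `p_season`, `mean_expr`, `n_obs`, `converged`.
#' @seealso [select_seasonal()], [common_seasonal()]
#' @export
cosinor_screen <- function(study, spec = model_spec(), meta = NULL) {
  if (inherits(study, "expression_study")) {
    M <- study$matrix
    meta <- study$samples
  } else {
    M <- as.matrix(study)
    if (is.null(meta)) stop("meta is required when study is a bare matrix")
  }
  stopifnot(ncol(M) == nrow(meta))
  m <- nrow(M)
  n <- ncol(M)
  if (n < 8L) stop("need at least 8 samples, got ", n)
  features <- rownames(M)
  if (is.null(features)) features <- paste0("f", seq_len(m))

  mf1 <- .build_model_frame(rep(0, n), meta, spec, seasonal = TRUE)
  rhs1 <- paste(mf1$rhs, collapse = " + ")
  rhs0 <- if (length(mf1$rhs) > 2L)
    paste(mf1$rhs[-(1:2)], collapse = " + ") else "1"

  if (length(mf1$rand) == 0L) {
    X1 <- model.matrix(as.formula(paste("~", rhs1)), data = mf1$dat)
    X0 <- model.matrix(as.formula(paste("~", rhs0)), data = mf1$dat)
    q1 <- qr(X1)
    q0 <- qr(X0)
    if (q1$rank < ncol(X1)) stop("rank-deficient seasonal design")
    tY <- t(M)
    rss1 <- colSums((tY - qr.fitted(q1, tY))^2)
    rss0 <- colSums((tY - qr.fitted(q0, tY))^2)
    cf <- qr.coef(q1, tY)
    b <- cf["sin_t", ]
    cc <- cf["cos_t", ]
    p1 <- ncol(X1)
    ll1 <- .gauss_loglik(rss1, n)
    ll0 <- .gauss_loglik(rss0, n)
    k1 <- p1 + 1L
    k0 <- ncol(X0) + 1L
    df2 <- n - p1
    stat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    pv <- pf(stat, 2, df2, lower.tail = FALSE)
    # degenerate rows: constant response or perfect seasonal fit
    const <- rss0 <= .Machine$double.eps * n
    stat[const] <- 0; pv[const] <- 1
    perfect <- !const & rss1 <= .Machine$double.eps * rss0
    stat[perfect] <- Inf; pv[perfect] <- 0
    res <- data.frame(
      feature_id = features, b_hat = unname(b), c_hat = unname(cc),
      loglik_s = ll1, loglik_0 = ll0,
      bic_s = k1 * log(n) - 2 * ll1, bic_0 = k0 * log(n) - 2 * ll0,
      statistic = stat, df = 2L,
      p_season = pmin(pmax(pv, .Machine$double.xmin), 1),
      mean_expr = rowMeans(M), n_obs = n, converged = TRUE,
      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    return(res)
  }

  # mixed-model path: template fits, then per-feature refits
  dat <- mf1$dat
  dat$y <- M[1L, ]
  fml1 <- as.formula(paste("y ~", rhs1, "+",
                           paste(sprintf("(1 | %s)", mf1$rand),
                                 collapse = " + ")))
  fml0 <- as.formula(paste("y ~", rhs0, "+",
                           paste(sprintf("(1 | %s)", mf1$rand),
                                 collapse = " + ")))
  ctrl <- .lmer_control()
  tmpl1 <- suppressMessages(lme4::lmer(fml1, data = dat, REML = FALSE,
                                       control = ctrl))
  tmpl0 <- suppressMessages(lme4::lmer(fml0, data = dat, REML = FALSE,
                                       control = ctrl))
  k1 <- attr(logLik(tmpl1), "df")
  k0 <- attr(logLik(tmpl0), "df")

  b <- cc <- ll1 <- ll0 <- stat <- pv <- rep(NA_real_, m)
  ok <- rep(FALSE, m)
  for (j in seq_len(m)) {
    yj <- M[j, ]
    f1 <- tryCatch(
      suppressMessages(suppressWarnings(lme4::refit(tmpl1, newresp = yj))),
      error = function(e) NULL)
    f0 <- tryCatch(
      suppressMessages(suppressWarnings(lme4::refit(tmpl0, newresp = yj))),
      error = function(e) NULL)
    if (is.null(f1) || is.null(f0)) next
    l1 <- as.numeric(logLik(f1))
    l0 <- as.numeric(logLik(f0))
    if (!is.finite(l1) || !is.finite(l0)) next
    if (l1 < l0 - 1e-6 * max(1, abs(l0))) next  # optimizer failure
    fe <- lme4::fixef(f1)
    b[j] <- unname(fe["sin_t"])
    cc[j] <- unname(fe["cos_t"])
    ll1[j] <- l1
    ll0[j] <- l0
    stat[j] <- 2 * max(l1 - l0, 0)
    pv[j] <- pchisq(stat[j], df = 2, lower.tail = FALSE)
    ok[j] <- TRUE
  }
  res <- data.frame(
    feature_id = features, b_hat = b, c_hat = cc,
    loglik_s = ll1, loglik_0 = ll0,
    bic_s = k1 * log(n) - 2 * ll1, bic_0 = k0 * log(n) - 2 * ll0,
    statistic = stat, df = 2L,
    p_season = pmin(pmax(pv, .Machine$double.xmin), 1),
    mean_expr = rowMeans(M), n_obs = n, converged = ok,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# ML Gaussian log-likelihood from a residual sum of squares
.gauss_loglik <- function(rss, n) {
  ll <- -n / 2 * (log(2 * pi) + 1 + log(rss / n))
  ll[rss <= 0] <- Inf
  ll
}
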