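#' Infer sample sex from Y-chromosome gene expression
#'
#' Computes the first principal component of the expression of four
#' Y-expressed marker genes (DDX3Y, KDM5D, USP9Y, RPS4Y1 by default) across
#' samples — PCA on centred, unscaled values, since the markers share units —
#' and orients it so that higher Y-gene expression maps to positive scores
#' (the sign of a principal component is otherwise arbitrary). Samples with
#' positive scores are called male, negative scores female; a score of
#' exactly zero is left uncalled (`NA`).
#'
#' @param expr feature-by-sample expression matrix (log2 scale) whose
#'   rownames include the marker genes.
#' @param markers character vector of Y-gene row names.
#' @return data frame: `sample_id`, `pc1_score`, `call` (`"M"`, `"F"` or
#'   `NA`).
#' @export
infer_sex <- function(expr,
                      markers = c("DDX3Y", "KDM5D", "USP9Y", "RPS4Y1")) {
  expr <- as.matrix(expr)
  missing <- setdiff(markers, rownames(expr))
  if (length(missing))
    stop("marker feature(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  sub <- t(expr[markers, , drop = FALSE])   # samples x markers
  if (all(apply(sub, 2L, sd) == 0))
    stop("zero-variance marker submatrix: no calls possible")
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1L]
  s <- pc$x[, 1L]
  # orient: score increases with mean marker expression
  flip <- if (sum(v) != 0) sum(v) < 0 else {
    cr <- suppressWarnings(stats::cor(s, rowMeans(sub)))
    !is.na(cr) && cr < 0
  }
  if (flip) s <- -s
  call <- ifelse(s > 0, "M", ifelse(s < 0, "F", NA_character_))
  ids <- colnames(expr)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(expr)))
  data.frame(sample_id = ids, pc1_score = unname(s), call = unname(call),
             stringsAsFactors = FALSE)
}

#' Test the effect of reported infections on summarized expression
#'
#' Summarizes the expression of a supplied feature set (e.g. the seasonal
#' genes of a cohort, or any co-expression-module subset) as the first
#' principal component across samples, then tests whether that summary
#' differs between samples with zero versus at least one reported infection
#' by one-way ANOVA. With two groups the F statistic equals the square of
#' the pooled-variance t statistic.
#'
#' @param expr feature-by-sample matrix restricted to the feature set of
#'   interest.
#' @param infection_status vector of group labels per sample, e.g. `0` /
#'   `1` for none vs at least one reported infection; coerced to factor.
#' @return list of class `infection_test`: `statistic` (F), `df` pair,
#'   `p_value`, `group_sizes`, `var_explained` (PC1's share of variance)
#'   and the per-sample `pc1_score`.
#' @export
infection_effect_test <- function(expr, infection_status) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(infection_status))
  g <- factor(infection_status)
  if (nlevels(g) < 2L || any(table(g) == 0L))
    stop("every status group must be non-empty")
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  s <- pc$x[, 1L]
  a <- anova(lm(s ~ g))
  structure(list(statistic = a$`F value`[1L],
                 df = c(a$Df[1L], a$Df[2L]),
                 p_value = a$`Pr(>F)`[1L],
                 group_sizes = as.vector(table(g)),
                 var_explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
                 pc1_score = s),
            class = "infection_test")
}

#' @export
print.infection_test <- function(x, ...) {
  cat(sprintf(
    "infection effect on PC1 (%.1f%% of variance): F = %.4g on (%d, %d) df, p = %.4g\n",
    100 * x$var_explained, x$statistic, x$df[1], x$df[2], x$p_value))
  cat("  group sizes:", paste(x$group_sizes, collapse = " / "), "\n")
  invisible(x)
}
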