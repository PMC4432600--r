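# Plain-text adapters. Matrices are TSV (first column feature_id, one column
# per sample), metadata and climate/FBC tables are CSV with ISO 8601 dates.
# Numeric values are written with %.17g so that write(read(x)) is
# byte-identical for canonical files.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_num_table <- function(df, path, sep) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

.check_dates <- function(x, what) {
  d <- suppressWarnings(as.Date(as.character(x)))
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("malformed date in ", what, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  d
}

#' Write an expression study to plain-text files
#'
#' Writes `<name>_expr.tsv` (matrix), `<name>_samples.csv` (metadata) and,
#' for simulated studies, `<name>_truth.tsv` into `dir`.
#'
#' @param study an `expression_study`.
#' @param dir output directory (created if needed).
#' @param name file-name stem.
#' @return invisibly, the paths written.
#' @export
write_expression_study <- function(study, dir, name = "cohort") {
  stopifnot(inherits(study, "expression_study") || is.list(study))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_expr <- file.path(dir, paste0(name, "_expr.tsv"))
  p_meta <- file.path(dir, paste0(name, "_samples.csv"))
  mat <- data.frame(feature_id = rownames(study$matrix),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(study$matrix)))
    mat[[colnames(study$matrix)[j]]] <- study$matrix[, j]
  .write_num_table(mat, p_expr, sep = "\t")
  meta <- study$samples
  meta$date_of_bleed <- format(as.Date(meta$date_of_bleed), "%Y-%m-%d")
  .write_num_table(meta, p_meta, sep = ",")
  paths <- c(expr = p_expr, samples = p_meta)
  if (!is.null(study$truth)) {
    p_truth <- file.path(dir, paste0(name, "_truth.tsv"))
    .write_num_table(study$truth, p_truth, sep = "\t")
    paths <- c(paths, truth = p_truth)
  }
  invisible(paths)
}

#' Read an expression study from plain-text files
#'
#' Counterpart of [write_expression_study()]. Extra metadata columns are
#' preserved and passed through; matrix columns must match the metadata's
#' `sample_id`s; dates are validated row by row.
#'
#' @param dir directory containing the files.
#' @param name file-name stem.
#' @return an `expression_study` (with `truth` when a truth sidecar exists).
#' @export
read_expression_study <- function(dir, name = "cohort") {
  p_expr <- file.path(dir, paste0(name, "_expr.tsv"))
  p_meta <- file.path(dir, paste0(name, "_samples.csv"))
  if (!file.exists(p_expr)) stop("missing expression matrix: ", p_expr)
  if (!file.exists(p_meta)) stop("missing sample metadata: ", p_meta)
  tab <- read.delim(p_expr, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id")
    stop("expression TSV must start with a feature_id column")
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- tab$feature_id
  if (!is.numeric(M)) stop("non-numeric values in expression matrix")
  meta <- read.csv(p_meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "date_of_bleed") %in% names(meta)))
    stop("sample metadata needs sample_id and date_of_bleed columns")
  meta$date_of_bleed <- .check_dates(meta$date_of_bleed, "sample metadata")
  if (!identical(colnames(M), meta$sample_id))
    stop("matrix columns do not match metadata sample_id order")
  out <- list(matrix = M, samples = meta, truth = NULL)
  p_truth <- file.path(dir, paste0(name, "_truth.tsv"))
  if (file.exists(p_truth))
    out$truth <- read.delim(p_truth, stringsAsFactors = FALSE)
  structure(out, class = "expression_study")
}

#' Write / read a daily climate series CSV
#'
#' Columns: `date` (ISO 8601), `tmean_c`, `sun_hours`.
#'
#' @param series a `climate_series` data frame.
#' @param path CSV path.
#' @return `write_climate_series`: invisibly, `path`.
#' @export
write_climate_series <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  .write_num_table(df, path, sep = ",")
  invisible(path)
}

#' @rdname write_climate_series
#' @export
read_climate_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "tmean_c", "sun_hours") %in% names(df)))
    stop("climate CSV needs date, tmean_c, sun_hours columns")
  df$date <- .check_dates(df$date, "climate series")
  class(df) <- c("climate_series", "data.frame")
  df
}

#' Write / read a full-blood-count table CSV
#'
#' Columns: `donor_id`, `date` and/or `month`, `age`, `sex`, one column per
#' response.
#'
#' @param table an `fbc_table` data frame.
#' @param path CSV path.
#' @return `write_fbc_table`: invisibly, `path`.
#' @export
write_fbc_table <- function(table, path) {
  df <- as.data.frame(table)
  if ("date" %in% names(df))
    df$date <- format(as.Date(df$date), "%Y-%m-%d")
  .write_num_table(df, path, sep = ",")
  invisible(path)
}

#' @rdname write_fbc_table
#' @export
read_fbc_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!("month" %in% names(df)) && !("date" %in% names(df)))
    stop("FBC CSV needs a month or date column")
  if ("date" %in% names(df)) {
    df$date <- .check_dates(df$date, "FBC table")
    if (!"month" %in% names(df)) df$month <- as.POSIXlt(df$date)$mon + 1L
  }
  class(df) <- c("fbc_table", "data.frame")
  df
}

#' Write a per-feature screen or classification result as TSV
#'
#' @param results data frame (e.g. from [cosinor_screen()] or
#'   [select_seasonal()]).
#' @param path TSV path.
#' @return invisibly, `path`.
#' @export
write_results_tsv <- function(results, path) {
  .write_num_table(as.data.frame(results), path, sep = "\t")
  invisible(path)
}
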