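# Independent least-squares oracle: normal equations, no shared code with
# the fitting paths under test.
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  list(beta = drop(beta), rss = rss)
}

# closed-form F statistic for adding the 2 seasonal columns
f_oracle <- function(rss0, rss1, n, p1) {
  ((rss0 - rss1) / 2) / (rss1 / (n - p1))
}

# minimal metadata frame: n bleeds on given dates, one subject each
meta_frame <- function(dates, subject = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    subject_id = if (is.null(subject)) sprintf("sub%03d", seq_len(n))
                 else subject,
    date_of_bleed = dates,
    age_at_bleed = seq(30, 40, length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    stringsAsFactors = FALSE)
}

# dates spread over one (non-leap) year
year_dates <- function(n, year = 2009) {
  as.Date(sprintf("%d-01-01", year)) + round(seq(0, 364, length.out = n))
}
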