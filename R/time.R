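#' Fraction of the year elapsed at a calendar date
#'
#' Maps a date to the cosinor time scale: the ordinal day of the year divided
#' by the number of days in that year (365, or 366 in leap years), so that
#' `t` lies in (0, 1] and one full year corresponds to one cycle of
#' `sin(2*pi*t)` / `cos(2*pi*t)`.
#'
#' @param dates a `Date` vector, or anything `as.Date()` accepts
#'   (ISO 8601 strings recommended).
#' @return numeric vector of year fractions in (0, 1].
#' @examples
#' day_fraction("2003-07-15")  # 196/365
#' day_fraction("2004-02-29")  # 60/366
#' @export
day_fraction <- function(dates) {
  d <- tryCatch(suppressWarnings(as.Date(dates)),
                error = function(e) rep(as.Date(NA), length(dates)))
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("unparseable date(s) at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  lt <- as.POSIXlt(d)
  yday <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | yr %% 400L == 0L
  yday / ifelse(leap, 366, 365)
}

# days-in-year helper for simulators
.days_in_year <- function(year) {
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  ifelse(leap, 366L, 365L)
}
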