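#' Convert calendar dates to decimal years
#'
#' All internal computation uses continuous decimal years with the
#' convention 1 year = 365.25 days, anchored so that 1970-01-01 maps to
#' 1970.0.  This removes leap-year ambiguity when splitting follow-up.
#'
#' @param x a `Date`, or something coercible to one (ISO-8601 strings).
#' @return numeric vector of decimal years.
#' @seealso [as_cal_date()] for the inverse.
#' @export
#' @examples
#' decimal_year(as.Date("1970-01-01"))  # 1970
decimal_year <- function(x) {
  if (!inherits(x, "Date")) x <- as.Date(x)
  1970 + as.numeric(x) / 365.25
}

#' Convert decimal years back to calendar dates
#'
#' Inverse of [decimal_year()] (to the nearest day).
#'
#' @param y numeric vector of decimal years.
#' @return a `Date` vector; `NA` maps to `NA`.
#' @export
as_cal_date <- function(y) {
  as.Date(round((y - 1970) * 365.25), origin = "1970-01-01")
}

## internal: NULL-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a
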