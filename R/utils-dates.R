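## Calendar-month helpers. Months are represented externally as Date values
## pinned to the first of the month; internally an integer month index
## (12 * year + month) makes lag arithmetic and rolling joins cheap.

#' Floor a date to the first day of its calendar month
#' @param x Date vector.
#' @return Date vector, first of each month.
#' @keywords internal
floor_month <- function(x) {
  as.Date(format(as.Date(x), "%Y-%m-01"))
}

## integer month index: Jan 2020 -> 24240
month_id <- function(x) {
  lt <- as.POSIXlt(as.Date(x))
  12L * (lt$year + 1900L) + lt$mon
}

month_from_id <- function(id) {
  as.Date(sprintf("%d-%02d-01", id %/% 12L, id %% 12L + 1L))
}

#' Whole calendar months from `from` to `to`
#' @param from,to Date vectors (day-of-month ignored).
#' @return integer vector of month differences.
#' @keywords internal
months_between <- function(from, to) {
  month_id(to) - month_id(from)
}

## mid-point of a month (day 15), used when only a month is known but an
## exact-date comparison against the era cutoff is needed
month_midpoint <- function(x) {
  as.Date(format(as.Date(x), "%Y-%m-15"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ttevax <- function(code, fmt, ...) {
  stop(sprintf("[%s] %s", code, sprintf(fmt, ...)), call. = FALSE)
}
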