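#' Day of year of a calendar date
#'
#' 1-based ordinal day with January 1 = day 1, true calendar (leap years
#' respected).
#'
#' @param date a `Date` vector (or something coercible with [as.Date()]).
#' @return integer vector of days of year.
#' @export
day_of_year <- function(date) {
  date <- as.Date(date)
  as.POSIXlt(date)$yday + 1L
}

#' Day of year relative to a reference year
#'
#' Days in December of the preceding year map to zero or negative values
#' (December 31 = day 0, December 28 = day -3), so a trailing window ending
#' on January 1 can be indexed without wrapping.
#'
#' @param date a `Date` vector.
#' @param year reference calendar year.
#' @return integer vector.
#' @keywords internal
rel_day_of_year <- function(date, year) {
  as.integer(as.Date(date) - as.Date(sprintf("%04d-01-01", as.integer(year)))) + 1L
}

#' Calendar date for a (possibly non-positive) day of year
#' @keywords internal
date_from_day <- function(year, day) {
  as.Date(sprintf("%04d-01-01", as.integer(year))) + (as.integer(day) - 1L)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Derive a sub-seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483629)
}

stop_validation <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}
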