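#' Mean daily temperature from four fixed observations
#'
#' The daily mean used throughout the pipeline is the climatological-station
#' average of four readings: `(t_max + t_min + t_06 + t_18) / 4`, where
#' `t_06` and `t_18` are the observations at 06:00 and 18:00 UTC.
#'
#' @param t_min,t_max daily minimum and maximum temperature (degrees C).
#' @param t_06,t_18 temperature at 06:00 / 18:00 UTC (degrees C).
#' @return numeric vector of daily mean temperatures.
#' @examples
#' daily_mean_temperature(t_min = 2, t_max = 10, t_06 = 4, t_18 = 8)  # 6
#' @export
daily_mean_temperature <- function(t_min, t_max, t_06, t_18) {
  args <- list(t_min = t_min, t_max = t_max, t_06 = t_06, t_18 = t_18)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || anyNA(args[[nm]]) || !all(is.finite(args[[nm]])))
      stop_validation("weather", "field '%s' must be finite numeric", nm)
  }
  (t_max + t_min + t_06 + t_18) / 4
}

#' Read a daily weather CSV
#'
#' Expected header: `date,t_min,t_max,t_06,t_18`; ISO-8601 dates, decimal
#' point, degrees Celsius, one row per day.
#'
#' @param path path to the CSV file.
#' @return a validated weather data frame sorted by date.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_weather(df)
}

#' Validate a daily weather table
#'
#' Checks the column set, coerces dates, rejects non-finite values (naming
#' the offending date and field), duplicate dates, and violations of the
#' ordering `t_min <= t_06, t_18 <= t_max` and `t_min <= t_max`.
#'
#' @param weather data frame with columns `date,t_min,t_max,t_06,t_18`.
#' @return the weather data frame, date-sorted.
#' @export
validate_weather <- function(weather) {
  req <- c("date", "t_min", "t_max", "t_06", "t_18")
  miss <- setdiff(req, names(weather))
  if (length(miss))
    stop_validation("weather", "missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(weather) == 0L)
    stop_validation("weather", "no rows")
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date))
    stop_validation("weather", "unparseable date(s)")
  for (nm in c("t_min", "t_max", "t_06", "t_18")) {
    bad <- !is.finite(weather[[nm]])
    if (any(bad))
      stop_validation("weather", "non-finite '%s' on %s", nm,
                      paste(weather$date[bad], collapse = ", "))
  }
  if (anyDuplicated(weather$date))
    stop_validation("weather", "duplicate date(s): %s",
                    paste(unique(weather$date[duplicated(weather$date)]), collapse = ", "))
  weather <- weather[order(weather$date), , drop = FALSE]
  bad <- weather$t_min > weather$t_max
  if (any(bad))
    stop_validation("weather", "t_min > t_max on %s",
                    paste(weather$date[bad], collapse = ", "))
  for (nm in c("t_06", "t_18")) {
    bad <- weather[[nm]] < weather$t_min | weather[[nm]] > weather$t_max
    if (any(bad))
      stop_validation("weather", "'%s' outside [t_min, t_max] on %s", nm,
                      paste(weather$date[bad], collapse = ", "))
  }
  rownames(weather) <- NULL
  weather
}

#' Fill short gaps in a daily weather series
#'
#' Missing calendar days are linearly interpolated per temperature field
#' when a gap spans at most `max_gap` consecutive days (with a warning
#' listing the filled dates); a longer gap aborts, since patched multi-day
#' stretches cannot support the running-mean features.
#'
#' @param weather validated weather data frame.
#' @param max_gap maximum number of consecutive missing days to interpolate.
#' @return a contiguous weather data frame.
#' @export
fill_weather_gaps <- function(weather, max_gap = 2L) {
  weather <- validate_weather(weather)
  all_days <- seq(min(weather$date), max(weather$date), by = "day")
  missing <- as.Date(setdiff(all_days, weather$date), origin = "1970-01-01")
  if (length(missing) == 0L) return(weather)
  runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
  too_long <- vapply(runs, length, 1L) > max_gap
  if (any(too_long))
    stop_validation("weather", "gap longer than %d day(s) starting %s", max_gap,
                    paste(vapply(runs[too_long], function(r) as.character(r[1]), ""),
                          collapse = ", "))
  out <- data.frame(date = all_days)
  xi <- as.numeric(weather$date)
  for (nm in c("t_min", "t_max", "t_06", "t_18"))
    out[[nm]] <- stats::approx(xi, weather[[nm]], xout = as.numeric(all_days))$y
  warning(sprintf("interpolated %d missing day(s): %s", length(missing),
                  paste(missing, collapse = ", ")), call. = FALSE)
  validate_weather(out)
}

#' Five-day trailing running means of a daily temperature statistic
#'
#' The running mean on day *d* averages the chosen daily statistic over the
#' five consecutive calendar days *d-4 ... d* (so the value indexed at
#' January 1 uses December 28 - January 1). `statistic = "max"` averages
#' daily maxima (used for Alnus and Corylus); `statistic = "mean"` averages
#' the four-observation daily mean (used for Betula, whose series starts on
#' March 5 with the window March 1-5).
#'
#' @param weather weather data frame (`date,t_min,t_max,t_06,t_18`); must
#'   cover the four days before `first_day`.
#' @param statistic `"max"` or `"mean"`.
#' @param first_day first day to index: a day-of-year integer (relative to
#'   `year`), an `"MM-DD"` string, or a `Date`.
#' @param year reference calendar year for day-of-year numbering; defaults
#'   to the year of the last date in `weather` (so a block spanning December
#'   of the previous year into spring is numbered by its spring year).
#' @param fill_gaps interpolate gaps of at most 2 days (see
#'   [fill_weather_gaps()]); with `FALSE` any gap is an error.
#' @return data frame `year, day, date, running_mean` with attributes
#'   `statistic` and `window` (= 5).
#' @export
running_means <- function(weather, statistic = c("max", "mean"), first_day,
                          year = NULL, fill_gaps = TRUE) {
  statistic <- match.arg(statistic)
  weather <- if (isTRUE(fill_gaps)) fill_weather_gaps(weather) else validate_weather(weather)
  if (any(diff(weather$date) != 1))
    stop_validation("met_features", "weather series has gaps; enable fill_gaps or repair input")
  if (is.null(year))
    year <- as.integer(format(max(weather$date), "%Y"))
  if (inherits(first_day, "Date")) {
    first_day <- rel_day_of_year(first_day, year)
  } else if (is.character(first_day)) {
    first_day <- rel_day_of_year(as.Date(sprintf("%04d-%s", year, first_day)), year)
  }
  first_day <- as.integer(first_day)

  day <- rel_day_of_year(weather$date, year)
  if (min(day) > first_day - 4L)
    stop_validation("met_features",
                    "insufficient leading history: first computable day is %d (need 4 days before day %d)",
                    min(day) + 4L, first_day)
  x <- switch(statistic,
              max  = weather$t_max,
              mean = daily_mean_temperature(weather$t_min, weather$t_max,
                                            weather$t_06, weather$t_18))
  rm5 <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 1))
  keep <- day >= first_day & !is.na(rm5)
  out <- data.frame(year = year, day = day[keep], date = weather$date[keep],
                    running_mean = rm5[keep])
  rownames(out) <- NULL
  attr(out, "statistic") <- statistic
  attr(out, "window") <- 5L
  class(out) <- c("running_means", "data.frame")
  out
}

#' Detect local minima in a running-mean temperature series
#'
#' A "local minimum" is a day preceded by at least `min_decrease_days`
#' strictly decreasing steps of the running mean and followed by at least
#' `min_increase_days` strictly increasing steps; such dips in the weeks
#' before a pollen season signal that the season is approaching. A tied
#' step breaks a run (strict inequalities), and days lacking full flanks at
#' the series edges are never reported.
#'
#' @param rms output of [running_means()], or any data frame with
#'   contiguous `day` and `running_mean` columns.
#' @param min_decrease_days,min_increase_days required flank lengths.
#' @param last_day optional day-of-year cap: minima after it are discarded
#'   (flanks may still use later values when available).
#' @return data frame `day, running_mean` of detected minima in ascending
#'   day order (zero rows if none).
#' @export
detect_local_minima <- function(rms, min_decrease_days = 2L,
                                min_increase_days = 2L, last_day = NULL) {
  if (is.null(rms) || nrow(rms) == 0L)
    return(data.frame(day = integer(), running_mean = numeric()))
  if (!all(c("day", "running_mean") %in% names(rms)))
    stop_validation("met_features", "need columns 'day' and 'running_mean'")
  if (any(diff(rms$day) != 1L))
    stop_validation("met_features", "day index is not contiguous")
  v <- rms$running_mean
  n <- length(v)
  kd <- as.integer(min_decrease_days)
  ki <- as.integer(min_increase_days)
  if (n < kd + ki + 1L)
    return(data.frame(day = integer(), running_mean = numeric()))
  d <- diff(v)
  idx <- integer(0)
  for (i in seq.int(kd + 1L, n - ki)) {
    if (all(d[(i - kd):(i - 1L)] < 0) && all(d[i:(i + ki - 1L)] > 0))
      idx <- c(idx, i)
  }
  out <- data.frame(day = rms$day[idx], running_mean = v[idx])
  if (!is.null(last_day))
    out <- out[out$day <= last_day, , drop = FALSE]
  rownames(out) <- NULL
  out
}
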