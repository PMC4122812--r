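#' Per-taxon season configuration
#'
#' Bundles the constants that define how a taxon's pollen season start is
#' computed and typed: the cumulative-sum threshold, the accumulation start
#' date, which daily temperature statistic feeds the 5-day running means,
#' the first indexed running-mean day, and the early/moderate/late (E/M/L)
#' day-of-year ranges.
#'
#' Defaults follow the Krakow monitoring conventions for the three taxa:
#' \describe{
#'   \item{Alnus}{threshold 5 grains cumulated since January 1, running
#'     means of daily maxima from January 1; E 12-36, M 37-60, L 61-84.}
#'   \item{Corylus}{threshold 5 since January 1, maxima from January 1;
#'     E 11-36, M 37-61, L 62-85.}
#'   \item{Betula}{threshold 15 since March 1, running means of the daily
#'     mean temperature from March 5; E 87-95, M 96-104, L 105-113.}
#' }
#'
#' @param taxon `"Alnus"`, `"Corylus"` or `"Betula"`.
#' @param cum_threshold,accumulation_start,rm_statistic,rm_first_day,season_type_bounds
#'   optional overrides of the per-taxon defaults. `accumulation_start` and
#'   `rm_first_day` are `"MM-DD"` strings; `season_type_bounds` is a named
#'   list of `c(lower, upper)` day-of-year pairs for `E`, `M`, `L`.
#' @return an object of class `taxon_config`.
#' @export
taxon_config <- function(taxon = c("Alnus", "Corylus", "Betula"),
                         cum_threshold = NULL, accumulation_start = NULL,
                         rm_statistic = NULL, rm_first_day = NULL,
                         season_type_bounds = NULL) {
  taxon <- match.arg(taxon)
  defaults <- list(
    Alnus = list(cum_threshold = 5, accumulation_start = "01-01",
                 rm_statistic = "max", rm_first_day = "01-01",
                 season_type_bounds = list(E = c(12L, 36L), M = c(37L, 60L), L = c(61L, 84L))),
    Corylus = list(cum_threshold = 5, accumulation_start = "01-01",
                   rm_statistic = "max", rm_first_day = "01-01",
                   season_type_bounds = list(E = c(11L, 36L), M = c(37L, 61L), L = c(62L, 85L))),
    Betula = list(cum_threshold = 15, accumulation_start = "03-01",
                  rm_statistic = "mean", rm_first_day = "03-05",
                  season_type_bounds = list(E = c(87L, 95L), M = c(96L, 104L), L = c(105L, 113L)))
  )[[taxon]]
  cfg <- list(
    taxon = taxon,
    cum_threshold = if (is.null(cum_threshold)) defaults$cum_threshold else cum_threshold,
    accumulation_start = if (is.null(accumulation_start)) defaults$accumulation_start else accumulation_start,
    rm_statistic = if (is.null(rm_statistic)) defaults$rm_statistic else rm_statistic,
    rm_first_day = if (is.null(rm_first_day)) defaults$rm_first_day else rm_first_day,
    season_type_bounds = if (is.null(season_type_bounds)) defaults$season_type_bounds else season_type_bounds
  )
  if (!is.numeric(cfg$cum_threshold) || cfg$cum_threshold <= 0)
    stop_validation("pollen_seasons", "cum_threshold must be > 0")
  b <- cfg$season_type_bounds
  if (!identical(sort(names(b)), c("E", "L", "M")))
    stop_validation("pollen_seasons", "season_type_bounds needs ranges E, M, L")
  if (!(b$E[1] <= b$E[2] && b$M[1] == b$E[2] + 1L && b$M[1] <= b$M[2] &&
        b$L[1] == b$M[2] + 1L && b$L[1] <= b$L[2]))
    stop_validation("pollen_seasons", "E/M/L ranges must be contiguous and non-overlapping")
  cfg$rm_statistic <- match.arg(cfg$rm_statistic, c("max", "mean"))
  class(cfg) <- "taxon_config"
  cfg
}

#' @export
print.taxon_config <- function(x, ...) {
  b <- x$season_type_bounds
  cat(sprintf("taxon_config: %s\n  cumulative threshold: %g grains from %s\n", x$taxon,
              x$cum_threshold, x$accumulation_start))
  cat(sprintf("  running means: 5-day %s from %s\n", x$rm_statistic, x$rm_first_day))
  cat(sprintf("  season types: E %d-%d, M %d-%d, L %d-%d\n",
              b$E[1], b$E[2], b$M[1], b$M[2], b$L[1], b$L[2]))
  invisible(x)
}

#' Derive E/M/L bounds by splitting an observed start-day range
#'
#' Auxiliary constructor: divides `[min_day, max_day]` into three
#' contiguous periods of (as near as possible) equal width. The bundled
#' per-taxon defaults take precedence for the reference taxa; this exists
#' for new sites or taxa where only the observed range is known.
#'
#' @param min_day,max_day earliest and latest observed season start
#'   (day-of-year).
#' @return named list of `E`, `M`, `L` ranges usable as
#'   `season_type_bounds` in [taxon_config()].
#' @export
season_type_bounds_from_range <- function(min_day, max_day) {
  min_day <- as.integer(min_day); max_day <- as.integer(max_day)
  if (max_day - min_day < 2L)
    stop_validation("pollen_seasons", "range too narrow to split into three periods")
  cuts <- round(min_day - 1L + (max_day - min_day + 1L) * c(1, 2) / 3)
  list(E = c(min_day, as.integer(cuts[1])),
       M = c(as.integer(cuts[1]) + 1L, as.integer(cuts[2])),
       L = c(as.integer(cuts[2]) + 1L, max_day))
}

#' Read a daily pollen concentration CSV
#'
#' Expected header: `date,taxon,concentration` with concentrations in
#' grains/m^3/day.
#'
#' @param path path to the CSV file.
#' @return data frame sorted by taxon and date.
#' @export
read_pollen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("date", "taxon", "concentration")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_validation("pollen_seasons", "missing column(s): %s", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_validation("pollen_seasons", "unparseable date(s)")
  if (any(!is.finite(df$concentration) | df$concentration < 0))
    stop_validation("pollen_seasons", "concentrations must be finite and non-negative")
  df <- df[order(df$taxon, df$date), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pollen season start by the cumulative-sum method
#'
#' The season start is the first day on or after the accumulation start
#' date whose cumulative daily pollen sum reaches (`>=`) the taxon
#' threshold (5 grains from January 1 for Alnus and Corylus, 15 grains from
#' March 1 for Betula).
#'
#' @param pollen data frame `date, concentration` (an optional `taxon`
#'   column is filtered to `config$taxon`), covering one pollen year.
#' @param config a [taxon_config()].
#' @param year reference year; defaults to the year of the last observation.
#' @return one-row data frame `taxon, year, day, date, season_type`
#'   (`season_type` is `NA` when the start day falls outside the typing
#'   ranges).
#' @export
season_start <- function(pollen, config, year = NULL) {
  if (!inherits(config, "taxon_config"))
    stop_validation("pollen_seasons", "config must be a taxon_config")
  if ("taxon" %in% names(pollen))
    pollen <- pollen[pollen$taxon == config$taxon, , drop = FALSE]
  if (nrow(pollen) == 0L)
    stop_validation("pollen_seasons", "no pollen rows for taxon %s", config$taxon)
  pollen$date <- as.Date(pollen$date)
  if (any(!is.finite(pollen$concentration) | pollen$concentration < 0))
    stop_validation("pollen_seasons", "concentrations must be finite and non-negative")
  if (is.null(year)) year <- as.integer(format(max(pollen$date), "%Y"))
  acc_start <- as.Date(sprintf("%04d-%s", year, config$accumulation_start))
  pollen <- pollen[pollen$date >= acc_start, , drop = FALSE]
  pollen <- pollen[order(pollen$date), , drop = FALSE]
  if (nrow(pollen) == 0L)
    stop_validation("pollen_seasons", "%s %d: no observations on or after %s",
                    config$taxon, year, acc_start)
  cs <- cumsum(pollen$concentration)
  hit <- which(cs >= config$cum_threshold)
  if (length(hit) == 0L)
    stop_validation("pollen_seasons",
                    "%s %d: no season detected (cumulative sum %.3g < threshold %g)",
                    config$taxon, year, cs[length(cs)], config$cum_threshold)
  start_date <- pollen$date[hit[1]]
  day <- rel_day_of_year(start_date, year)
  data.frame(taxon = config$taxon, year = year, day = day, date = start_date,
             season_type = classify_season_type(day, config, strict = FALSE),
             stringsAsFactors = FALSE)
}

#' Classify a season start day as early / moderate / late
#'
#' @param day day-of-year vector.
#' @param config a [taxon_config()] carrying the E/M/L bounds.
#' @param strict error when a day falls outside all ranges (observed starts
#'   can precede or follow the historical bounds); with `strict = FALSE`
#'   such days get `NA`.
#' @return character vector of `"E"`, `"M"`, `"L"` (or `NA`).
#' @export
classify_season_type <- function(day, config, strict = TRUE) {
  b <- config$season_type_bounds
  out <- rep(NA_character_, length(day))
  for (type in c("E", "M", "L"))
    out[day >= b[[type]][1] & day <= b[[type]][2]] <- type
  if (strict && anyNA(out))
    stop_validation("pollen_seasons", "day(s) %s outside typing range [%d, %d]",
                    paste(day[is.na(out)], collapse = ", "), b$E[1], b$L[2])
  out
}

#' Descriptive statistics of season start days
#'
#' Computes the summary reported for multi-year season-start series: n,
#' mean, median, sample standard deviation, coefficient of variation
#' (100 * SD / mean, in percent), range, and the 95% confidence interval of
#' the mean (t distribution, n - 1 df).
#'
#' @param starts numeric vector of start days, or a data frame with a
#'   `day` column.
#' @return object of class `season_stats` (a named list).
#' @export
season_stats <- function(starts) {
  days <- if (is.data.frame(starts)) starts$day else starts
  days <- as.numeric(days[!is.na(days)])
  n <- length(days)
  if (n < 2L)
    stop_validation("pollen_seasons", "need at least 2 start days (SD undefined for n = %d)", n)
  m <- mean(days); s <- stats::sd(days)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  out <- list(n = n, mean = m, median = stats::median(days), sd = s,
              cv = 100 * s / m, min = min(days), max = max(days),
              ci_lower = m - half, ci_upper = m + half)
  class(out) <- "season_stats"
  out
}

#' @export
print.season_stats <- function(x, digits = 1, ...) {
  cat(sprintf("season starts (n = %d): mean %.1f, median %.1f, SD %.1f, CV %.1f%%\n",
              x$n, x$mean, x$median, x$sd, x$cv))
  cat(sprintf("  range %g-%g, 95%% CI of mean [%.1f, %.1f]\n",
              x$min, x$max, x$ci_lower, x$ci_upper))
  invisible(x)
}
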