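#' Pipeline run configuration
#'
#' Collects the tunable constants of the full analysis: the per-taxon
#' season configurations, the onset window, the training exclusion, the
#' decision threshold, the local-minimum flank lengths and the gap
#' interpolation limit.
#'
#' @param taxa named list of [taxon_config()] objects; defaults to the
#'   three bundled taxa.
#' @param window onset window in days (default 10).
#' @param exclusion training exclusion in days (default 3).
#' @param threshold decision threshold (default 0.5, strict `>`).
#' @param min_decrease_days,min_increase_days local-minimum flank lengths.
#' @param interpolation_limit maximum weather gap (days) filled by linear
#'   interpolation.
#' @return object of class `run_config`.
#' @export
run_config <- function(taxa = NULL, window = 10L, exclusion = 3L,
                       threshold = 0.5, min_decrease_days = 2L,
                       min_increase_days = 2L, interpolation_limit = 2L) {
  if (is.null(taxa))
    taxa <- list(Alnus = taxon_config("Alnus"), Corylus = taxon_config("Corylus"),
                 Betula = taxon_config("Betula"))
  if (!(window > exclusion && exclusion >= 0))
    stop_validation("cli_app", "need window > exclusion >= 0")
  if (!(threshold > 0 && threshold < 1))
    stop_validation("cli_app", "threshold must be in (0, 1)")
  structure(list(taxa = taxa, window = as.integer(window),
                 exclusion = as.integer(exclusion), threshold = threshold,
                 min_decrease_days = as.integer(min_decrease_days),
                 min_increase_days = as.integer(min_increase_days),
                 interpolation_limit = as.integer(interpolation_limit)),
            class = "run_config")
}

# Split a multi-year weather table into per-season-year blocks: rows from
# December belong to the following year's season.
split_weather_by_season_year <- function(weather) {
  weather <- validate_weather(weather)
  m <- as.integer(format(weather$date, "%m"))
  y <- as.integer(format(weather$date, "%Y"))
  season_year <- ifelse(m == 12L, y + 1L, y)
  split(weather, season_year)
}

#' Run the full onset-model pipeline
#'
#' For each requested taxon: determines per-year season starts from the
#' pollen series (cumulative-sum rule), computes 5-day running means up to
#' each year's start day, detects local minima, assembles the binary
#' training cases, fits the logistic onset model and produces the
#' in-sample classification table.
#'
#' @param weather multi-year daily weather table (rows from December are
#'   attached to the following season year; each year's block must be
#'   contiguous up to gaps within the interpolation limit).
#' @param pollen daily pollen table (`date, taxon, concentration`).
#' @param config a [run_config()].
#' @param taxa character vector of taxa to run; defaults to those present
#'   in both `config` and `pollen`.
#' @return object of class `pipeline_result`: per-taxon lists with
#'   `season_starts`, `minima`, `cases`, `fit` and `classification`.
#' @export
run_pipeline <- function(weather, pollen, config = run_config(), taxa = NULL) {
  if (is.null(weather) || nrow(weather) == 0L)
    stop_validation("cli_app", "weather: empty input")
  if (is.null(pollen) || nrow(pollen) == 0L)
    stop_validation("cli_app", "pollen: empty input")
  pollen$date <- as.Date(pollen$date)
  if (is.null(taxa))
    taxa <- intersect(names(config$taxa), unique(pollen$taxon))
  if (length(taxa) == 0L)
    stop_validation("cli_app", "no taxa shared between config and pollen input")
  blocks <- split_weather_by_season_year(weather)
  out <- list()
  for (tx in taxa) {
    cfg <- config$taxa[[tx]]
    ptx <- pollen[pollen$taxon == tx, , drop = FALSE]
    pyears <- sort(unique(as.integer(format(ptx$date, "%Y"))))
    starts <- list(); minima <- list()
    for (yr in pyears) {
      if (!as.character(yr) %in% names(blocks)) next
      st <- tryCatch(
        season_start(ptx[format(ptx$date, "%Y") == as.character(yr), , drop = FALSE],
                     cfg, year = yr),
        error = function(e)
          stop_validation("cli_app", "%s %d / season_start: %s", tx, yr,
                          conditionMessage(e)))
      rms <- tryCatch(
        running_means(blocks[[as.character(yr)]], statistic = cfg$rm_statistic,
                      first_day = cfg$rm_first_day, year = yr),
        error = function(e)
          stop_validation("cli_app", "%s %d / running_means: %s", tx, yr,
                          conditionMessage(e)))
      # training convention: the feature series runs to the season start day
      rms <- rms[rms$day <= st$day, , drop = FALSE]
      mins <- detect_local_minima(rms, config$min_decrease_days,
                                  config$min_increase_days)
      if (nrow(mins)) {
        mins <- data.frame(taxon = tx, year = yr, day = mins$day,
                           t5 = mins$running_mean, stringsAsFactors = FALSE)
        minima[[as.character(yr)]] <- mins
      }
      starts[[as.character(yr)]] <- st
    }
    if (length(starts) == 0L)
      stop_validation("cli_app", "%s: no year with both weather and pollen data", tx)
    starts <- do.call(rbind, starts)
    minima <- if (length(minima)) do.call(rbind, minima)
      else data.frame(taxon = character(), year = integer(), day = integer(),
                      t5 = numeric())
    rownames(starts) <- rownames(minima) <- NULL
    cases <- build_training_cases(minima, starts, window = config$window,
                                  exclusion = config$exclusion)
    fit <- fit_onset_model(cases)
    out[[tx]] <- list(season_starts = starts, minima = minima, cases = cases,
                      fit = fit,
                      classification = classification_table(fit, cases,
                                                            threshold = config$threshold))
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  for (tx in names(x)) {
    r <- x[[tx]]
    cat(sprintf("== %s: %d season(s), %d minima, %d training case(s) ==\n",
                tx, nrow(r$season_starts), nrow(r$minima), nrow(r$cases)))
    print(r$classification)
  }
  invisible(x)
}

#' Fit on training years, verify on held-out years
#'
#' Fits the onset model using only `fit_years` and then applies the fixed
#' coefficients to every local minimum of each `verify_years` season
#' (without the training exclusion, and with the feature series extended
#' past the start day, as verification requires).
#'
#' @inheritParams run_pipeline
#' @param fit_years,verify_years disjoint integer year sets.
#' @return list with `fit_result` (a `pipeline_result` on the training
#'   years) and `verification` (per-taxon forecast tables).
#' @export
holdout_verify <- function(weather, pollen, config = run_config(),
                           fit_years, verify_years, taxa = NULL) {
  if (length(intersect(fit_years, verify_years)))
    stop_validation("cli_app", "fit_years and verify_years overlap: %s",
                    paste(intersect(fit_years, verify_years), collapse = ", "))
  pollen$date <- as.Date(pollen$date)
  pyear <- as.integer(format(pollen$date, "%Y"))
  blocks <- split_weather_by_season_year(weather)
  wyear <- as.integer(names(blocks))
  fit_weather <- do.call(rbind, blocks[wyear %in% fit_years])
  fit_res <- run_pipeline(fit_weather, pollen[pyear %in% fit_years, , drop = FALSE],
                          config, taxa = taxa)
  verification <- list()
  for (tx in names(fit_res)) {
    cfg <- config$taxa[[tx]]
    rows <- list()
    for (yr in sort(verify_years)) {
      if (!as.character(yr) %in% names(blocks)) next
      ptx <- pollen[pollen$taxon == tx & pyear == yr, , drop = FALSE]
      if (nrow(ptx) == 0L) next
      st <- season_start(ptx, cfg, year = yr)
      rms <- running_means(blocks[[as.character(yr)]], statistic = cfg$rm_statistic,
                           first_day = cfg$rm_first_day, year = yr)
      mins <- detect_local_minima(rms, config$min_decrease_days,
                                  config$min_increase_days, last_day = st$day)
      if (nrow(mins) == 0L) next
      rows[[as.character(yr)]] <- verify_forecasts(
        fit_res[[tx]]$fit, mins, start_day = st$day, window = config$window,
        threshold = config$threshold, year = yr)
    }
    verification[[tx]] <- if (length(rows)) do.call(rbind, rows)
      else data.frame()
  }
  list(fit_result = fit_res, verification = verification)
}

#' Write pipeline reports to CSV/JSON files
#'
#' Per taxon: season starts and training cases as CSV, classification
#' counts/percentages and fitted coefficients as JSON.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_reports <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tx in names(result)) {
    r <- result[[tx]]
    p1 <- file.path(dir, sprintf("%s_season_starts.csv", tolower(tx)))
    st <- r$season_starts
    st$date <- format(st$date, "%Y-%m-%d")
    utils::write.csv(st, p1, row.names = FALSE, quote = FALSE)
    p2 <- file.path(dir, sprintf("%s_training_cases.csv", tolower(tx)))
    utils::write.csv(r$cases, p2, row.names = FALSE, quote = FALSE)
    p3 <- file.path(dir, sprintf("%s_classification.json", tolower(tx)))
    cl <- r$classification
    jsonlite::write_json(
      list(taxon = tx, counts = list(tp = cl$tp, fn = cl$fn, fp = cl$fp, tn = cl$tn),
           pct_yes = cl$pct_yes, pct_no = cl$pct_no, pct_overall = cl$pct_overall,
           coefficients = as.list(coef(r$fit))),
      p3, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p1, p2, p3)
  }
  invisible(paths)
}
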