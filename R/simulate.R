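#' Simulation scenario for synthetic weather and pollen studies
#'
#' Defines the generative process used to test the pipeline end to end:
#' daily mean temperature is a seasonal sinusoid (coldest in mid-January)
#' plus AR(1) Gaussian noise; the four daily observations are derived from
#' the mean by fixed offsets plus small independent noise and re-ordered so
#' that `t_min <= t_06, t_18 <= t_max`; season onset is generated through
#' the logistic model's own hazard at the detected local minima; pollen
#' counts are laid down so the cumulative-sum rule recovers the intended
#' start day exactly.
#'
#' @param n_years number of simulated study years.
#' @param seed base RNG seed; every generator derives per-year sub-seeds
#'   from it, so a scenario is fully reproducible.
#' @param taxon taxon whose [taxon_config()] conventions the study follows.
#' @param winter_mean mean daily temperature at the mid-January trough
#'   (degrees C).
#' @param amplitude peak-to-trough annual amplitude of the seasonal cycle
#'   (degrees C).
#' @param ar1 AR(1) coefficient of the daily noise, `0 <= ar1 < 1`.
#' @param noise_sd stationary standard deviation of the daily noise
#'   (degrees C).
#' @param offsets named numeric offsets generating `t_max`, `t_min`,
#'   `t_06`, `t_18` from the daily mean (degrees C).
#' @param offset_noise_sd SD of the small independent noise added to each
#'   offset observation (degrees C).
#' @param coefficients true onset coefficients driving the simulated
#'   hazard; defaults to the Alnus reference set.
#' @param peak_concentration peak of the bell-shaped post-onset pollen
#'   curve (grains/m^3/day).
#' @param season_sd width (SD, days) of the post-onset pollen curve.
#' @param first_year calendar year assigned to year index 1.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_years = 20L, seed = 1L,
                                taxon = c("Alnus", "Corylus", "Betula"),
                                winter_mean = -2, amplitude = 21,
                                ar1 = 0.7, noise_sd = 3,
                                offsets = c(t_max = 4, t_min = -4, t_06 = -2, t_18 = 1),
                                offset_noise_sd = 0.5,
                                coefficients = NULL,
                                peak_concentration = 120, season_sd = 7,
                                first_year = 1991L) {
  taxon <- match.arg(taxon)
  if (is.null(coefficients)) coefficients <- krakow_coefficients(taxon)
  coefficients <- as_coefficients(coefficients)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_validation("synthetic_data", "noise_sd must be > 0")
  if (!is.numeric(ar1) || abs(ar1) >= 1)
    stop_validation("synthetic_data", "need |ar1| < 1")
  if (amplitude < 0)
    stop_validation("synthetic_data", "amplitude must be >= 0")
  if (!all(c("t_max", "t_min", "t_06", "t_18") %in% names(offsets)))
    stop_validation("synthetic_data", "offsets must name t_max, t_min, t_06, t_18")
  sc <- list(n_years = as.integer(n_years), seed = as.integer(seed),
             taxon = taxon, config = taxon_config(taxon),
             winter_mean = winter_mean, amplitude = amplitude, ar1 = ar1,
             noise_sd = noise_sd, offsets = offsets,
             offset_noise_sd = offset_noise_sd, coefficients = coefficients,
             peak_concentration = peak_concentration, season_sd = season_sd,
             first_year = as.integer(first_year))
  class(sc) <- "simulation_scenario"
  sc
}

#' Read a simulation scenario from a YAML file
#'
#' Recognized keys match the arguments of [simulation_scenario()];
#' `coefficients` may be a mapping with `beta0`, `beta_day`, `beta_t`.
#'
#' @param path path to a YAML file.
#' @return a `simulation_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$offsets)) y$offsets <- unlist(y$offsets)
  if (!is.null(y$coefficients) && is.list(y$coefficients))
    y$coefficients <- onset_coefficients(y$coefficients$beta0,
                                         y$coefficients$beta_day,
                                         y$coefficients$beta_t,
                                         taxon = y$coefficients$taxon %||% NA_character_)
  do.call(simulation_scenario, y)
}

#' Simulate one winter/spring daily temperature series
#'
#' Generates a weather block from December 20 of the preceding calendar
#' year through April 30, deterministic given `(scenario$seed,
#' year_index)`. The daily mean follows the scenario's seasonal sinusoid
#' plus AR(1) noise; `t_min`/`t_max`/`t_06`/`t_18` are the mean plus the
#' scenario offsets and small independent noise, then reconciled so the
#' daily ordering invariants hold.
#'
#' @param scenario a [simulation_scenario()].
#' @param year_index 1-based study year index.
#' @param attempt re-draw counter (changes the sub-seed; used when a year
#'   must be resimulated because no onset was triggered).
#' @return a weather data frame (`date,t_min,t_max,t_06,t_18`).
#' @export
simulate_temperature <- function(scenario, year_index, attempt = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  year <- scenario$first_year + as.integer(year_index) - 1L
  dates <- seq(as.Date(sprintf("%04d-12-20", year - 1L)),
               as.Date(sprintf("%04d-04-30", year)), by = "day")
  nd <- length(dates)
  doy <- rel_day_of_year(dates, year)
  seasonal <- scenario$winter_mean +
    scenario$amplitude * (1 - cos(2 * pi * (doy - 15) / 365.25)) / 2
  with_seed(derive_seed(scenario$seed, year_index * 131L + attempt), {
    innov_sd <- scenario$noise_sd * sqrt(1 - scenario$ar1^2)
    eps <- numeric(nd)
    eps[1] <- stats::rnorm(1, 0, scenario$noise_sd)
    for (i in 2:nd)
      eps[i] <- scenario$ar1 * eps[i - 1] + stats::rnorm(1, 0, innov_sd)
    tmean <- seasonal + eps
    obs <- lapply(c("t_max", "t_min", "t_06", "t_18"), function(nm)
      tmean + scenario$offsets[[nm]] + stats::rnorm(nd, 0, scenario$offset_noise_sd))
    names(obs) <- c("t_max", "t_min", "t_06", "t_18")
    t_min <- do.call(pmin, obs)
    t_max <- do.call(pmax, obs)
    data.frame(date = dates, t_min = t_min, t_max = t_max,
               t_06 = pmin(pmax(obs$t_06, t_min), t_max),
               t_18 = pmin(pmax(obs$t_18, t_min), t_max))
  })
}

#' Simulate a season onset through the model's own hazard
#'
#' Traverses the local minima in ascending day order, drawing a Bernoulli
#' trial at each with success probability given by the onset model; on the
#' first success at day *d* the season start is drawn uniformly from
#' `{d + 3, ..., d + window}`, so induced training labels are clean under
#' the 3-day exclusion. When no minimum succeeds the year is flagged
#' untriggered and the caller may resimulate.
#'
#' Draws use the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param minima data frame with `day` and `t5` (or `running_mean`)
#'   columns, ascending in day.
#' @param coefficients true onset coefficients.
#' @param window onset window in days (default 10).
#' @param exclusion minimum start offset (default 3).
#' @return list with `triggered` (logical), `start_day` (`NA` when
#'   untriggered) and `trigger_day` (day of the successful minimum).
#' @export
simulate_onset <- function(minima, coefficients, window = 10L, exclusion = 3L) {
  if (!("t5" %in% names(minima)) && "running_mean" %in% names(minima))
    minima$t5 <- minima$running_mean
  if (is.null(minima) || nrow(minima) == 0L)
    stop_validation("synthetic_data", "empty minima list")
  if (is.unsorted(minima$day, strictly = TRUE))
    stop_validation("synthetic_data", "minima must be in ascending day order")
  p <- onset_probability(coefficients, minima$day, minima$t5)
  u <- stats::runif(nrow(minima))
  hit <- which(u < p)
  if (length(hit) == 0L)
    return(list(triggered = FALSE, start_day = NA_integer_, trigger_day = NA_integer_))
  d <- minima$day[hit[1]]
  offset <- sample(seq.int(exclusion, window), 1L)
  list(triggered = TRUE, start_day = as.integer(d + offset),
       trigger_day = as.integer(d))
}

#' Simulate a daily pollen series with a prescribed season start
#'
#' Inverts the cumulative-sum rule: concentrations before `start_day` sum
#' to strictly less than the taxon threshold, the threshold is first
#' reached exactly on `start_day`, and after it a noisy bell-shaped season
#' curve follows (clamped at zero). By construction
#' `season_start(simulate_pollen(s, ...), config)` recovers `s`.
#'
#' Draws use the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param start_day intended season start (day-of-year).
#' @param scenario a [simulation_scenario()] (supplies the taxon config and
#'   the season shape).
#' @param year calendar year of the simulated season.
#' @return data frame `date, taxon, concentration`.
#' @export
simulate_pollen <- function(start_day, scenario, year) {
  cfg <- scenario$config
  acc_start <- rel_day_of_year(as.Date(sprintf("%04d-%s", year, cfg$accumulation_start)), year)
  if (start_day < acc_start)
    stop_validation("synthetic_data", "start_day %d precedes accumulation start %d",
                    start_day, acc_start)
  days <- seq.int(acc_start, max(start_day + 4L * scenario$season_sd, 120L))
  conc <- numeric(length(days))
  pre <- days < start_day
  if (any(pre)) {
    # scatter a sub-threshold pre-season total over a few random days
    pre_total <- stats::runif(1, 0, 0.9) * cfg$cum_threshold
    k <- min(sum(pre), stats::rpois(1, 2) + 1L)
    at <- which(pre)[sample.int(sum(pre), k)]
    wts <- stats::runif(k)
    conc[at] <- pre_total * wts / sum(wts)
  }
  i0 <- which(days == start_day)
  bell <- scenario$peak_concentration *
    exp(-0.5 * ((days - start_day - 2 * scenario$season_sd) / scenario$season_sd)^2)
  post <- days >= start_day
  conc[post] <- pmax(bell[post] * (1 + stats::rnorm(sum(post), 0, 0.3)), 0)
  # guarantee the threshold is first reached exactly on start_day
  deficit <- cfg$cum_threshold - sum(conc[seq_len(i0 - 1L)])
  # the 0.01 margin keeps the contract intact under 4-decimal CSV rounding
  conc[i0] <- max(conc[i0], deficit + 0.01 + abs(stats::rnorm(1, 0, 1)))
  data.frame(date = date_from_day(year, days), taxon = cfg$taxon,
             concentration = conc, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic multi-year study
#'
#' Runs the full generative chain for each study year — temperature series,
#' running means, local minima, hazard-driven onset (resimulating the
#' year's weather when no minimum triggers), and a pollen series consistent
#' with the cumulative-sum rule — and optionally writes `weather.csv`,
#' `pollen.csv` and a `truth.json` file recording the scenario, the true
#' coefficients and the per-year minima, trigger and start days.
#'
#' @param scenario a [simulation_scenario()].
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @param max_attempts re-draw limit per year for untriggered onsets.
#' @return (invisibly when writing) a list with `weather`, `pollen`,
#'   `truth` and, if written, `paths`.
#' @export
make_study <- function(scenario, dir = NULL, max_attempts = 50L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  cfg <- scenario$config
  weather_all <- list(); pollen_all <- list(); years <- list()
  for (i in seq_len(scenario$n_years)) {
    year <- scenario$first_year + i - 1L
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      wx <- simulate_temperature(scenario, i, attempt = attempt)
      rms <- running_means(wx, statistic = cfg$rm_statistic,
                           first_day = cfg$rm_first_day, year = year)
      minima <- detect_local_minima(rms)
      if (nrow(minima) == 0L) next
      onset <- with_seed(derive_seed(scenario$seed, i * 977L + attempt),
                         simulate_onset(minima, scenario$coefficients))
      if (!onset$triggered) next
      pol <- with_seed(derive_seed(scenario$seed, i * 613L + attempt),
                       simulate_pollen(onset$start_day, scenario, year))
      done <- TRUE
      break
    }
    if (!done)
      stop_validation("synthetic_data",
                      "year %d: no onset triggered in %d attempts", year, max_attempts)
    weather_all[[i]] <- wx
    pollen_all[[i]] <- pol
    years[[i]] <- list(year = year, start_day = onset$start_day,
                       trigger_day = onset$trigger_day, attempts = attempt,
                       minima = list(day = minima$day, t5 = minima$running_mean))
  }
  truth <- list(
    taxon = scenario$taxon, seed = scenario$seed, n_years = scenario$n_years,
    coefficients = list(beta0 = scenario$coefficients$beta0,
                        beta_day = scenario$coefficients$beta_day,
                        beta_t = scenario$coefficients$beta_t),
    onset_offset_range = c(3L, 10L),
    years = years)
  out <- list(weather = do.call(rbind, weather_all),
              pollen = do.call(rbind, pollen_all), truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(weather = file.path(dir, "weather.csv"),
               pollen = file.path(dir, "pollen.csv"),
               truth = file.path(dir, "truth.json"))
    wx <- out$weather
    wx$date <- format(wx$date, "%Y-%m-%d")
    for (nm in c("t_min", "t_max", "t_06", "t_18")) wx[[nm]] <- round(wx[[nm]], 4)
    utils::write.csv(wx, paths[["weather"]], row.names = FALSE, quote = FALSE)
    pol <- out$pollen
    pol$date <- format(pol$date, "%Y-%m-%d")
    pol$concentration <- round(pol$concentration, 4)
    utils::write.csv(pol, paths[["pollen"]], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
    out$paths <- paths
    return(invisible(out))
  }
  out
}
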