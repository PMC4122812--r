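# Shared fixtures and independent brute-force oracles.

# Weather table whose four observations all equal the given daily means
# (so both the "max" and "mean" statistics equal the input series).
flat_weather <- function(values, end_date = as.Date("2000-04-30")) {
  dates <- seq(end_date - length(values) + 1L, end_date, by = "day")
  data.frame(date = dates, t_min = values, t_max = values,
             t_06 = values, t_18 = values)
}

# Weather table with a fixed spread around the daily mean.
spread_weather <- function(means, end_date = as.Date("2000-04-30")) {
  dates <- seq(end_date - length(means) + 1L, end_date, by = "day")
  data.frame(date = dates, t_min = means - 3, t_max = means + 3,
             t_06 = means - 1, t_18 = means + 1)
}

# Brute-force trailing k-term window mean.
bf_window_mean <- function(x, i, k = 5L) mean(x[(i - k + 1L):i])

# Exhaustive day-by-day flank scan for local minima.
bf_local_minima <- function(day, value, kd = 2L, ki = 2L) {
  idx <- integer(0)
  n <- length(value)
  for (i in seq_len(n)) {
    if (i <= kd || i > n - ki) next
    ok <- TRUE
    for (j in seq_len(kd)) if (!(value[i - j] > value[i - j + 1L])) ok <- FALSE
    for (j in seq_len(ki)) if (!(value[i + j] > value[i + j - 1L])) ok <- FALSE
    if (ok) idx <- c(idx, i)
  }
  data.frame(day = day[idx], running_mean = value[idx])
}

# Exhaustive cumulative scan for the season start index.
bf_season_start_index <- function(conc, threshold) {
  total <- 0
  for (i in seq_along(conc)) {
    total <- total + conc[i]
    if (total >= threshold) return(i)
  }
  NA_integer_
}

# Direct logistic evaluation (independent of onset_probability).
bf_logistic <- function(beta, day, t5) {
  eta <- beta[1] + beta[2] * day + beta[3] * t5
  exp(eta) / (1 + exp(eta))
}

# Clean synthetic training cases drawn straight from the model: days
# uniform on [5, 80], t5 ~ N(0, 5^2), Bernoulli labels.
clean_cases <- function(n, beta, seed) {
  set.seed(seed)
  day <- runif(n, 5, 80)
  t5 <- rnorm(n, 0, 5)
  p <- plogis(beta[1] + beta[2] * day + beta[3] * t5)
  data.frame(day = day, t5 = t5, label = rbinom(n, 1, p))
}

# One simulated study reduced to training cases via the full feature
# chain (temperature -> running means -> minima -> hazard onset), with
# untriggered years contributing all-zero labels.
study_training_cases <- function(scenario, window = 10L, exclusion = 3L) {
  cases <- list()
  for (i in seq_len(scenario$n_years)) {
    year <- scenario$first_year + i - 1L
    wx <- simulate_temperature(scenario, i)
    rms <- running_means(wx, statistic = scenario$config$rm_statistic,
                         first_day = scenario$config$rm_first_day, year = year)
    minima <- detect_local_minima(rms)
    if (nrow(minima) == 0L) next
    onset <- with_seed_pkg(derive_seed_pkg(scenario$seed, i * 977L + 1L),
                           simulate_onset(minima, scenario$coefficients))
    if (onset$triggered) {
      starts <- data.frame(year = year, day = onset$start_day)
      minima$year <- year
      cases[[i]] <- build_training_cases(minima, starts, window = window,
                                         exclusion = exclusion)
    } else {
      cases[[i]] <- data.frame(taxon = NA_character_, year = year,
                               day = minima$day, t5 = minima$running_mean,
                               label = 0L)
    }
  }
  do.call(rbind, cases)
}

# Internal helpers re-exposed for test use.
with_seed_pkg <- getFromNamespace("with_seed", "pollenonset")
derive_seed_pkg <- getFromNamespace("derive_seed", "pollenonset")
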