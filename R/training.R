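#' Build binary training cases from local minima and season starts
#'
#' Each retained local minimum becomes one case labelled 1 when the
#' season started within `window` days after it (offsets 1..window) and 0
#' otherwise. Minima falling fewer than `exclusion` days before the start
#' (offsets below `exclusion`) are dropped from the training set, as are
#' minima on or after the start day; both rules apply to training only, not
#' to forecast verification.
#'
#' @param minima data frame of detected minima with columns `year`, `day`,
#'   and the running-mean temperature as `t5` (or `running_mean`); an
#'   optional `taxon` column is carried through.
#' @param starts data frame of season starts with columns `year`, `day`
#'   (e.g. rows from [season_start()]); every year present in `minima` must
#'   have a start.
#' @param window label window in days (default 10).
#' @param exclusion minimum offset retained for training (default 3 days).
#' @return data frame `taxon, year, day, t5, label` ordered by year then
#'   day.
#' @export
build_training_cases <- function(minima, starts, window = 10L, exclusion = 3L) {
  if (!all(c("year", "day") %in% names(minima)))
    stop_validation("training_data", "minima need columns 'year' and 'day'")
  if (!("t5" %in% names(minima))) {
    if ("running_mean" %in% names(minima)) {
      minima$t5 <- minima$running_mean
    } else {
      stop_validation("training_data", "minima need a 't5' (or 'running_mean') column")
    }
  }
  if (!all(c("year", "day") %in% names(starts)))
    stop_validation("training_data", "starts need columns 'year' and 'day'")
  if (window <= exclusion || exclusion < 0)
    stop_validation("training_data", "need window > exclusion >= 0")

  no_start <- setdiff(unique(minima$year), starts$year[!is.na(starts$day)])
  if (length(no_start))
    stop_validation("training_data", "year(s) with minima but no season start: %s",
                    paste(sort(no_start), collapse = ", "))
  start_of <- stats::setNames(starts$day, as.character(starts$year))
  s <- as.numeric(start_of[as.character(minima$year)])
  offset <- s - minima$day
  # keep pre-start minima only, and drop those within the exclusion band
  keep <- offset >= max(exclusion, 1L)
  out <- data.frame(
    taxon = if ("taxon" %in% names(minima)) minima$taxon[keep]
      else rep(NA_character_, sum(keep)),
    year = minima$year[keep], day = minima$day[keep], t5 = minima$t5[keep],
    label = as.integer(offset[keep] <= window),
    stringsAsFactors = FALSE)
  out <- out[order(out$year, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verify onset forecasts against an observed season start
#'
#' Applies fixed (previously fitted) coefficients to each local minimum of
#' a verification year: the forecast is YES when the modelled probability
#' strictly exceeds the threshold, and the observed outcome is YES when the
#' season actually started within `window` days after the minimum. Unlike
#' training, no minima are excluded for being close to the start.
#'
#' @param coefficients fixed model coefficients (see [onset_probability()]).
#' @param minima data frame with `day` and `t5` (or `running_mean`) columns.
#' @param start_day observed season start (day-of-year).
#' @param window observation window in days (default 10).
#' @param threshold decision threshold (default 0.5, strict `>`).
#' @param year optional year label carried into the output.
#' @return data frame `year, day, t5, probability, forecast, observed,
#'   correct`.
#' @export
verify_forecasts <- function(coefficients, minima, start_day, window = 10L,
                             threshold = 0.5, year = NA_integer_) {
  if (!("t5" %in% names(minima)) && "running_mean" %in% names(minima))
    minima$t5 <- minima$running_mean
  if (!all(c("day", "t5") %in% names(minima)))
    stop_validation("training_data", "minima need columns 'day' and 't5'")
  p <- onset_probability(coefficients, minima$day, minima$t5)
  offset <- start_day - minima$day
  observed <- ifelse(offset >= 1 & offset <= window, "YES", "NO")
  forecast <- ifelse(p > threshold, "YES", "NO")
  data.frame(year = year, day = minima$day, t5 = minima$t5, probability = p,
             forecast = forecast, observed = observed,
             correct = forecast == observed, stringsAsFactors = FALSE)
}

#' In-sample classification table of an onset model
#'
#' Cross-tabulates observed labels against the `probability > threshold`
#' forecast on the training cases (in-sample accounting) and reports the
#' percentage correct among observed YES cases, among observed NO cases,
#' and overall.
#'
#' @param fit an [fit_onset_model()] result, or fixed coefficients.
#' @param cases training cases (`day`, `t5`, `label`); defaults to the
#'   cases stored in the fit.
#' @param threshold decision threshold (default 0.5, strict `>`).
#' @return object of class `classification_table`: a list with counts
#'   `tp, fn, fp, tn` and percentages `pct_yes, pct_no, pct_overall`.
#' @export
classification_table <- function(fit, cases = NULL, threshold = 0.5) {
  if (is.null(cases)) {
    if (inherits(fit, "onset_fit")) cases <- fit$data
    else stop_validation("training_data", "cases must be supplied")
  }
  if (nrow(cases) == 0L)
    stop_validation("training_data", "no cases")
  p <- onset_probability(fit, cases$day, cases$t5)
  yes <- p > threshold
  y <- cases$label == 1L
  tp <- sum(yes & y); fn <- sum(!yes & y)
  fp <- sum(yes & !y); tn <- sum(!yes & !y)
  out <- list(tp = tp, fn = fn, fp = fp, tn = tn,
              pct_yes = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
              pct_no = if (fp + tn > 0) 100 * tn / (fp + tn) else NA_real_,
              pct_overall = 100 * (tp + tn) / (tp + fn + fp + tn),
              threshold = threshold, n = nrow(cases))
  class(out) <- "classification_table"
  out
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("classification at threshold %.2f (n = %d)\n", x$threshold, x$n))
  cat(sprintf("  observed YES: %d predicted YES, %d predicted NO (%.2f%% correct)\n",
              x$tp, x$fn, x$pct_yes))
  cat(sprintf("  observed NO:  %d predicted YES, %d predicted NO (%.2f%% correct)\n",
              x$fp, x$tn, x$pct_no))
  cat(sprintf("  overall: %.2f%% correct\n", x$pct_overall))
  invisible(x)
}
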