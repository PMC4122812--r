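#' Logistic onset-model coefficients
#'
#' The onset model gives the probability that a pollen season starts within
#' ten days of a pre-season temperature "local minimum":
#' \deqn{P = \frac{e^{\beta_0 + \beta_{day} Day + \beta_t t_5}}{1 +
#'   e^{\beta_0 + \beta_{day} Day + \beta_t t_5}}}
#' where *Day* is the day-of-year of the minimum and \eqn{t_5} the 5-day
#' running-mean temperature on that day.
#'
#' @param beta0 intercept.
#' @param beta_day coefficient per day-of-year.
#' @param beta_t coefficient per degree Celsius of the running mean.
#' @param taxon optional taxon label.
#' @param source optional free-text provenance label.
#' @return object of class `onset_coefficients`.
#' @seealso [krakow_coefficients()] for the bundled reference sets.
#' @export
onset_coefficients <- function(beta0, beta_day, beta_t, taxon = NA_character_,
                               source = "user") {
  b <- c(beta0 = as.numeric(beta0), beta_day = as.numeric(beta_day),
         beta_t = as.numeric(beta_t))
  if (!all(is.finite(b)))
    stop_validation("logit_model", "coefficients must be finite")
  structure(list(beta0 = b[["beta0"]], beta_day = b[["beta_day"]],
                 beta_t = b[["beta_t"]], taxon = taxon, source = source),
            class = "onset_coefficients")
}

#' @export
coef.onset_coefficients <- function(object, ...) {
  c(beta0 = object$beta0, beta_day = object$beta_day, beta_t = object$beta_t)
}

#' @export
print.onset_coefficients <- function(x, ...) {
  cat(sprintf("onset model coefficients%s:\n",
              if (is.na(x$taxon)) "" else paste0(" (", x$taxon, ")")))
  print(coef(x))
  invisible(x)
}

as_coefficients <- function(x) {
  if (inherits(x, "onset_coefficients")) return(x)
  if (inherits(x, "onset_fit")) return(x$coefficients)
  if (is.numeric(x) && length(x) == 3L)
    return(onset_coefficients(x[[1]], x[[2]], x[[3]]))
  stop_validation("logit_model", "cannot interpret coefficients of class %s",
                  paste(class(x), collapse = "/"))
}

#' Read / write onset coefficients as JSON
#'
#' The JSON schema is `{taxon, beta0, beta_day, beta_t, source}`.
#'
#' @param path file path.
#' @return for the reader, an [onset_coefficients()] object.
#' @export
read_onset_coefficients <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  onset_coefficients(j$beta0, j$beta_day, j$beta_t,
                     taxon = j$taxon %||% NA_character_,
                     source = j$source %||% "file")
}

#' @rdname read_onset_coefficients
#' @param x an `onset_coefficients` object.
#' @export
write_onset_coefficients <- function(x, path) {
  x <- as_coefficients(x)
  jsonlite::write_json(list(taxon = x$taxon, beta0 = x$beta0,
                            beta_day = x$beta_day, beta_t = x$beta_t,
                            source = x$source),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference onset coefficients (Krakow, 1991-2010)
#'
#' The bundled two-predictor logistic coefficient sets fitted to the
#' Krakow 1991-2010 monitoring data: intercept, day-of-year and 5-day
#' running-mean temperature coefficients of
#' (-3.588, 0.066, 0.185) for Alnus, (-4.155, 0.074, 0.215) for Corylus and
#' (-25.413, 0.274, 0.352) for Betula.
#'
#' @param taxon `"Alnus"`, `"Corylus"` or `"Betula"`.
#' @return an [onset_coefficients()] object.
#' @export
krakow_coefficients <- function(taxon = c("Alnus", "Corylus", "Betula")) {
  taxon <- match.arg(taxon)
  path <- system.file("extdata", "coefficients",
                      paste0(tolower(taxon), ".json"), package = "pollenonset")
  if (nzchar(path)) return(read_onset_coefficients(path))
  # fallback when running from a source tree
  sets <- list(Alnus = c(-3.588, 0.066, 0.185),
               Corylus = c(-4.155, 0.074, 0.215),
               Betula = c(-25.413, 0.274, 0.352))[[taxon]]
  onset_coefficients(sets[1], sets[2], sets[3], taxon = taxon,
                     source = "Krakow 1991-2010 reference fit")
}

#' Onset probability at a local minimum
#'
#' Evaluates the logistic model `plogis(beta0 + beta_day * day + beta_t *
#' t5)`, numerically stable for linear predictors up to around +/-700.
#'
#' @param coefficients an [onset_coefficients()], an [fit_onset_model()]
#'   result, or a numeric triple `(beta0, beta_day, beta_t)`.
#' @param day day-of-year of the local minimum (vectorized).
#' @param t5 5-day running-mean temperature at the minimum, degrees C
#'   (vectorized).
#' @return numeric vector of probabilities in (0, 1).
#' @export
onset_probability <- function(coefficients, day, t5) {
  cf <- as_coefficients(coefficients)
  if (!all(is.finite(day)) || !all(is.finite(t5)))
    stop_validation("logit_model", "day and t5 must be finite")
  stats::plogis(cf$beta0 + cf$beta_day * day + cf$beta_t * t5)
}

#' Point forecast from the onset model
#'
#' Applies the strict `probability > threshold` decision rule (a probability
#' of exactly 0.5 forecasts NO).
#'
#' @inheritParams onset_probability
#' @param threshold decision threshold (default 0.5).
#' @return data frame `day, t5, probability, forecast` with forecast
#'   `"YES"`/`"NO"`.
#' @export
forecast_onset <- function(coefficients, day, t5, threshold = 0.5) {
  p <- onset_probability(coefficients, day, t5)
  data.frame(day = day, t5 = t5, probability = p,
             forecast = ifelse(p > threshold, "YES", "NO"),
             stringsAsFactors = FALSE)
}

#' Odds multiplier for a predictor change
#'
#' Multiplicative change in onset odds when a predictor moves by `delta`
#' units: `exp(beta * delta)`. With the Corylus reference coefficients,
#' ten additional days multiply the odds by about 2.1 and five additional
#' degrees by about 2.9.
#'
#' @inheritParams onset_probability
#' @param predictor `"day"` or `"t5"`.
#' @param delta change in the predictor (days or degrees C).
#' @return numeric odds ratio.
#' @export
odds_multiplier <- function(coefficients, predictor = c("day", "t5"), delta) {
  cf <- as_coefficients(coefficients)
  predictor <- match.arg(predictor)
  beta <- switch(predictor, day = cf$beta_day, t5 = cf$beta_t)
  exp(beta * delta)
}

#' Day at which the onset probability reaches a given level
#'
#' Solves `beta0 + beta_day * d + beta_t * t5 = logit(p)` for `d` in closed
#' form: the day on which, at a fixed running-mean temperature, the modelled
#' onset probability crosses `p`.
#'
#' @inheritParams onset_probability
#' @param t5 running-mean temperature at which to solve (degrees C).
#' @param p probability level in (0, 1); default 0.5, the decision
#'   threshold.
#' @return list with the real-valued solution `day` and `nearest_day`
#'   (rounded to the nearest integer).
#' @export
day_at_probability <- function(coefficients, t5, p = 0.5) {
  cf <- as_coefficients(coefficients)
  if (cf$beta_day == 0)
    stop_validation("logit_model", "beta_day is 0: probability never crosses %g in day", p)
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop_validation("logit_model", "p must be in (0, 1)")
  d <- (stats::qlogis(p) - cf$beta0 - cf$beta_t * t5) / cf$beta_day
  list(day = d, nearest_day = as.integer(round(d)))
}

#' Probability curve over a range of days
#'
#' Vectorized [onset_probability()] at a fixed running-mean temperature;
#' strictly increasing in day whenever `beta_day > 0`.
#'
#' @inheritParams onset_probability
#' @param t5 fixed running-mean temperature (degrees C).
#' @param days vector of days-of-year.
#' @return data frame `day, t5, probability`.
#' @export
probability_curve <- function(coefficients, t5, days) {
  if (length(days) == 0L)
    stop_validation("logit_model", "empty day range")
  data.frame(day = days, t5 = t5,
             probability = onset_probability(coefficients, days, t5))
}

# Bernoulli log-likelihood in the log-sum-exp form: sum(y*eta - log(1+e^eta)),
# with log1p(exp(eta)) computed without overflow for large |eta|.
logit_loglik <- function(eta, y) {
  log1pe <- ifelse(eta > 30, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - log1pe)
}

#' Fit the two-predictor logistic onset model
#'
#' Maximum-likelihood fit of the onset model on labelled training cases by
#' Newton-Raphson (iteratively reweighted least squares). Convergence is
#' declared when the largest score component falls below `tol_score` or the
#' largest parameter change below `tol_param`; perfect separation and a
#' singular information matrix are detected and reported as errors rather
#' than returning diverged estimates.
#'
#' The returned fit carries the full diagnostic set: standard errors from
#' the inverse observed information, t statistics with n - 3 residual
#' degrees of freedom and their two-sided p-values, Wald chi-square
#' statistics (against chi-square with 1 df), odds ratios `exp(beta)` with
#' 95% CIs (normal approximation on the coefficient scale, exponentiated),
#' and the likelihood-ratio goodness-of-fit chi-square against the
#' intercept-only model (2 df).
#'
#' @param cases data frame with columns `day`, `t5` and `label` (0/1), as
#'   produced by [build_training_cases()].
#' @param max_iter,tol_score,tol_param Newton iteration controls.
#' @return object of class `onset_fit`.
#' @export
fit_onset_model <- function(cases, max_iter = 100L, tol_score = 1e-8,
                            tol_param = 1e-10) {
  req <- c("day", "t5", "label")
  miss <- setdiff(req, names(cases))
  if (length(miss))
    stop_validation("logit_model", "missing column(s): %s", paste(miss, collapse = ", "))
  y <- as.numeric(cases$label)
  if (!all(y %in% c(0, 1)))
    stop_validation("logit_model", "labels must be 0/1")
  n <- length(y)
  if (n < 10L)
    stop_validation("logit_model", "need at least 10 cases (got %d)", n)
  if (length(unique(y)) < 2L)
    stop_validation("logit_model", "both labels must be present")
  X <- cbind(beta0 = 1, beta_day = as.numeric(cases$day), beta_t = as.numeric(cases$t5))
  if (!all(is.finite(X)))
    stop_validation("logit_model", "non-finite predictors")

  beta <- c(stats::qlogis(mean(y)), 0, 0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    info <- crossprod(X * w, X)
    if (all(abs(p - y) < 1e-8))
      stop_validation("logit_model",
                      "perfect separation: fitted probabilities reached the labels, estimates diverge")
    step <- tryCatch(solve(info, score), error = function(e)
      stop_validation("logit_model", "singular information matrix: %s", conditionMessage(e)))
    # step-halving keeps the likelihood non-decreasing on hard instances
    ll0 <- logit_loglik(eta, y)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      if (logit_loglik(drop(X %*% cand), y) >= ll0 - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    delta <- cand - beta
    beta <- cand
    if (max(abs(score)) < tol_score || max(abs(delta)) < tol_param) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 1e3)
      stop_validation("logit_model",
                      "perfect separation suspected: coefficients diverging (max |beta| > 1000)")
  }
  if (!converged)
    warning("fit_onset_model: not converged after ", max_iter, " iterations",
            call. = FALSE)

  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  info <- crossprod(X * w, X)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  tval <- beta / se
  df_resid <- n - 3L
  ll_full <- logit_loglik(eta, y)
  pbar <- mean(y)
  ll_null <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  lr <- 2 * (ll_full - ll_null)
  z <- stats::qnorm(0.975)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)

  fit <- list(
    coefficients = onset_coefficients(beta[1], beta[2], beta[3],
                                      source = "fit_onset_model"),
    se = se,
    t = tval,
    df_resid = df_resid,
    p_t = 2 * stats::pt(-abs(tval), df = df_resid),
    wald = tval^2,
    p_wald = stats::pchisq(tval^2, df = 1, lower.tail = FALSE),
    odds_ratio = exp(beta),
    ci_coef = ci,
    ci_odds_ratio = exp(ci),
    loglik = ll_full,
    loglik_null = ll_null,
    lr_chisq = lr,
    lr_df = 2L,
    p_lr = stats::pchisq(lr, df = 2, lower.tail = FALSE),
    n = n,
    iterations = iter,
    converged = converged,
    vcov = vcov,
    data = cases
  )
  class(fit) <- "onset_fit"
  fit
}

#' @export
coef.onset_fit <- function(object, ...) coef(object$coefficients)

#' @export
vcov.onset_fit <- function(object, ...) object$vcov

#' @export
logLik.onset_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("Logistic onset model (n = %d, %s, %d iteration(s))\n", x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  tab <- cbind(estimate = coef(x), se = x$se, `t` = x$t, `p(t)` = x$p_t,
               `Wald chi2` = x$wald, `p(Wald)` = x$p_wald, OR = x$odds_ratio)
  print(round(tab, 4))
  cat(sprintf("LR chi2(2) = %.3f, p = %.3g (logLik %.3f vs null %.3f)\n",
              x$lr_chisq, x$p_lr, x$loglik, x$loglik_null))
  invisible(x)
}

#' @export
summary.onset_fit <- function(object, ...) object

#' Predict onset probabilities from a fitted model
#'
#' @param object an `onset_fit`.
#' @param newdata data frame with `day` and `t5` columns; defaults to the
#'   training cases.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.onset_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  onset_probability(object$coefficients, newdata$day, newdata$t5)
}
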