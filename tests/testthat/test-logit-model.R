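test_that("onset probability equals the closed-form logistic", {
  cf <- krakow_coefficients("Alnus")
  expect_equal(round(onset_probability(cf, 60, 5.6), 2), 0.80)
  expect_equal(onset_probability(onset_coefficients(0, 0, 0), 37, -3), 0.5)

  set.seed(301)
  for (rep in 1:10) {
    beta <- rnorm(3, 0, c(3, 0.1, 0.3))
    day <- runif(100, 0, 120); t5 <- rnorm(100, 0, 8)
    expect_equal(onset_probability(onset_coefficients(beta[1], beta[2], beta[3]),
                                   day, t5),
                 bf_logistic(beta, day, t5), tolerance = 1e-12)
  }
  # numerically stable at extreme linear predictors
  expect_equal(onset_probability(onset_coefficients(700, 0, 0), 0, 0), 1)
  expect_equal(onset_probability(onset_coefficients(-700, 0, 0), 0, 0), 0)
  expect_error(onset_probability(cf, NA, 1), "finite")
})

test_that("logistic symmetry: negating the linear predictor flips the probability", {
  set.seed(302)
  beta <- c(-2, 0.05, 0.2)
  day <- runif(50, 0, 100); t5 <- rnorm(50, 0, 5)
  p1 <- onset_probability(onset_coefficients(beta[1], beta[2], beta[3]), day, t5)
  p2 <- onset_probability(onset_coefficients(-beta[1], -beta[2], -beta[3]), day, t5)
  expect_equal(p1 + p2, rep(1, 50), tolerance = 1e-12)
})

test_that("maximum-likelihood fit recovers known coefficients and matches glm", {
  truth <- c(-3.588, 0.065, 0.185)
  cases <- clean_cases(2000, truth, seed = 303)
  fit <- fit_onset_model(cases)
  expect_true(fit$converged)
  # each estimate within 3 estimated SEs of the truth
  expect_true(all(abs(coef(fit) - truth) < 3 * fit$se))
  # score at the optimum is numerically zero
  p <- predict(fit)
  X <- cbind(1, cases$day, cases$t5)
  expect_lt(max(abs(crossprod(X, cases$label - p))), 1e-6)

  # independent cross-check: glm's IRLS on the same data
  g <- glm(label ~ day + t5, data = cases, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(fit$lr_chisq, g$null.deviance - g$deviance, tolerance = 1e-6)
})

test_that("a label-flip symmetric dataset has intercept zero", {
  set.seed(304)
  half <- data.frame(day = rnorm(100), t5 = rnorm(100), label = 1L)
  mirrored <- data.frame(day = -half$day, t5 = -half$t5, label = 0L)
  fit <- fit_onset_model(rbind(half, mirrored))
  expect_lt(abs(coef(fit)[["beta0"]]), 1e-6)
})

test_that("fit diagnostics satisfy the algebraic identities", {
  cases <- clean_cases(400, c(-3, 0.06, 0.2), seed = 305)
  fit <- fit_onset_model(cases)
  b <- coef(fit)
  expect_equal(fit$odds_ratio, exp(b), tolerance = 1e-12)
  expect_equal(unname(fit$wald), unname((b / fit$se)^2), tolerance = 1e-12)
  expect_equal(fit$ci_odds_ratio, exp(fit$ci_coef), tolerance = 1e-12)
  expect_equal(fit$ci_coef[, "lower"], b - qnorm(0.975) * fit$se, tolerance = 1e-12)
  expect_gte(fit$lr_chisq, 0)
  expect_equal(fit$lr_chisq, 2 * (fit$loglik - fit$loglik_null), tolerance = 1e-12)
  expect_equal(fit$df_resid, nrow(cases) - 3L)
  expect_equal(unname(fit$p_wald),
               pchisq(unname(fit$wald), 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("fit is equivariant under affine rescaling of t5", {
  cases <- clean_cases(600, c(-3.5, 0.07, 0.2), seed = 306)
  fit <- fit_onset_model(cases)
  scaled <- cases
  mu <- mean(scaled$t5); sig <- sd(scaled$t5)
  scaled$t5 <- (scaled$t5 - mu) / sig
  fit2 <- fit_onset_model(scaled)
  back <- c(coef(fit2)[["beta0"]] - coef(fit2)[["beta_t"]] * mu / sig,
            coef(fit2)[["beta_day"]],
            coef(fit2)[["beta_t"]] / sig)
  expect_equal(unname(coef(fit)), back, tolerance = 1e-6)
})

test_that("degenerate training inputs are rejected with clear errors", {
  cases <- clean_cases(50, c(0, 0.05, 0.1), seed = 307)
  expect_error(fit_onset_model(cases[1:5, ]), "at least 10")
  ones <- cases; ones$label <- 1L
  expect_error(fit_onset_model(ones), "both labels")
  # perfectly separated labels
  set.seed(309)
  sep <- data.frame(day = c(1:10, 41:50), t5 = rnorm(20),
                    label = rep(c(0L, 1L), each = 10))
  expect_error(fit_onset_model(sep), "separation")
  # a constant predictor makes the information singular
  const <- data.frame(day = 7, t5 = rnorm(40), label = rbinom(40, 1, 0.5))
  expect_error(fit_onset_model(const), "singular")
})

test_that("odds multipliers reproduce the reference interpretations", {
  expect_equal(round(odds_multiplier(krakow_coefficients("Corylus"), "day", 10), 1), 2.1)
  expect_equal(round(odds_multiplier(krakow_coefficients("Alnus"), "t5", 5), 1), 2.5)
  expect_equal(round(odds_multiplier(krakow_coefficients("Corylus"), "t5", 5), 1), 2.9)
  expect_equal(round(odds_multiplier(krakow_coefficients("Betula"), "day", 10)), 15)
  expect_equal(round(odds_multiplier(krakow_coefficients("Betula"), "t5", 5)), 6)
  expect_equal(odds_multiplier(krakow_coefficients("Alnus"), "day", 0), 1)
})

test_that("day_at_probability solves the crossing in closed form", {
  cf <- krakow_coefficients("Alnus")
  sol <- day_at_probability(cf, t5 = -4, p = 0.5)
  expect_equal(sol$nearest_day, 66L)

  # t5 chosen so beta0 + beta_t*t5 = 0 puts the 0.5 crossing at day 0
  t5star <- -cf$beta0 / cf$beta_t
  expect_equal(day_at_probability(cf, t5star, 0.5)$day, 0, tolerance = 1e-10)

  set.seed(308)
  for (rep in 1:50) {
    c2 <- onset_coefficients(rnorm(1, 0, 3), rnorm(1, 0.1, 0.05) + 0.01,
                             rnorm(1, 0, 0.3))
    p <- runif(1, 0.05, 0.95); t5 <- rnorm(1, 0, 5)
    d <- day_at_probability(c2, t5, p)$day
    expect_equal(onset_probability(c2, d, t5), p, tolerance = 1e-10)
  }
  expect_error(day_at_probability(onset_coefficients(1, 0, 1), 0), "beta_day")
})

test_that("probability curves are monotone and dominated by warmer temperatures", {
  cf <- krakow_coefficients("Alnus")
  cold <- probability_curve(cf, t5 = -4, days = 1:90)
  warm <- probability_curve(cf, t5 = 6, days = 1:90)
  expect_true(all(diff(cold$probability) > 0))
  expect_true(all(warm$probability > cold$probability))
  expect_equal(cold$probability, onset_probability(cf, 1:90, -4))
  expect_error(probability_curve(cf, 0, integer(0)), "empty")
})

test_that("coefficients round-trip through the JSON schema", {
  cf <- onset_coefficients(-3.588, 0.066, 0.185, taxon = "Alnus", source = "test")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_onset_coefficients(cf, path)
  got <- read_onset_coefficients(path)
  expect_equal(coef(got), coef(cf))
  expect_equal(got$taxon, "Alnus")
})
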