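one_year_minima <- function(days, t5 = NULL, year = 2000) {
  data.frame(year = year, day = days,
             t5 = if (is.null(t5)) rep(0, length(days)) else t5)
}

test_that("labels follow the 1..window offset rule and the exclusion band", {
  starts <- data.frame(year = 2000, day = 66)
  # start 6 days after the minimum -> YES
  expect_equal(build_training_cases(one_year_minima(60), starts)$label, 1L)
  # 25 days ahead -> NO
  starts2 <- data.frame(year = 2000, day = 55)
  expect_equal(build_training_cases(one_year_minima(30), starts2)$label, 0L)
  # less than 3 days before the start -> dropped from training
  expect_equal(nrow(build_training_cases(one_year_minima(53), starts2)), 0L)
  # on/after the start -> dropped
  expect_equal(nrow(build_training_cases(one_year_minima(55), starts2)), 0L)
  expect_equal(nrow(build_training_cases(one_year_minima(60), starts2)), 0L)
})

test_that("labels equal the window inequality over an exhaustive offset grid", {
  for (s_minus_d in 1:30) {
    starts <- data.frame(year = 2000, day = 50 + s_minus_d)
    got <- build_training_cases(one_year_minima(50), starts,
                                window = 10, exclusion = 3)
    if (s_minus_d < 3) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$label, as.integer(s_minus_d <= 10))
    }
  }
})

test_that("a year with minima but no season start is an error", {
  starts <- data.frame(year = 2001, day = 66)
  expect_error(build_training_cases(one_year_minima(60, year = 2000), starts),
               "no season start")
})

test_that("widening the window only turns 0-labels into 1-labels", {
  set.seed(201)
  minima <- data.frame(year = rep(2000:2004, each = 4),
                       day = rep(c(10, 25, 40, 55), 5), t5 = rnorm(20))
  starts <- data.frame(year = 2000:2004, day = sample(58:80, 5))
  narrow <- build_training_cases(minima, starts, window = 8)
  wide <- build_training_cases(minima, starts, window = 14)
  expect_true(all(wide$label >= narrow$label))
})

test_that("labels ignore temperature values entirely", {
  minima <- one_year_minima(c(30, 50), t5 = c(-12, 5))
  shifted <- minima
  shifted$t5 <- shifted$t5 * 1.8 + 32
  starts <- data.frame(year = 2000, day = 56)
  expect_equal(build_training_cases(minima, starts)$label,
               build_training_cases(shifted, starts)$label)
})

test_that("verification keeps near-start minima and applies the strict 0.5 rule", {
  cf <- krakow_coefficients("Alnus")
  rows <- verify_forecasts(cf, data.frame(day = c(10, 18, 36, 43, 60),
                                          t5 = c(4.3, 0.0, -12.4, -8.6, 5.6)),
                           start_day = 66)
  expect_equal(rows$forecast, c("NO", "NO", "NO", "NO", "YES"))
  expect_equal(rows$observed, c("NO", "NO", "NO", "NO", "YES"))
  expect_equal(round(rows$probability[5], 2), 0.80)

  # offset-1 minima are still scored in verification (no training exclusion)
  r1 <- verify_forecasts(cf, data.frame(day = 93, t5 = 5), start_day = 94)
  expect_equal(r1$observed, "YES")

  # an all-zero model gives probability exactly 0.5: strict ">" forecasts NO
  r0 <- verify_forecasts(onset_coefficients(0, 0, 0),
                         data.frame(day = c(10, 60), t5 = c(-5, 5)),
                         start_day = 66)
  expect_equal(r0$probability, c(0.5, 0.5))
  expect_equal(r0$forecast, c("NO", "NO"))
})

test_that("verification forecasts equal independently thresholded logistic values", {
  set.seed(202)
  for (rep in 1:25) {
    beta <- rnorm(3, 0, c(2, 0.05, 0.2))
    minima <- data.frame(day = sort(sample(5:90, 6)), t5 = rnorm(6, 0, 5))
    rows <- verify_forecasts(onset_coefficients(beta[1], beta[2], beta[3]),
                             minima, start_day = 95)
    p_bf <- bf_logistic(beta, minima$day, minima$t5)
    expect_equal(rows$probability, p_bf, tolerance = 1e-12)
    expect_equal(rows$forecast, ifelse(p_bf > 0.5, "YES", "NO"))
  }
})

test_that("classification table counts and percentages match a hand count", {
  # all observed NO, all predicted NO -> 100 % overall
  cases <- data.frame(day = rep(5, 12), t5 = rep(-30, 12), label = 0L)
  ct <- classification_table(krakow_coefficients("Alnus"), cases)
  expect_equal(ct$pct_overall, 100)

  # percentages are pure count arithmetic: TP=6 FN=8 FP=3 TN=50
  counts <- list(tp = 6, fn = 8, fp = 3, tn = 50)
  expect_equal(round(100 * counts$tp / (counts$tp + counts$fn), 2), 42.86)
  expect_equal(round(100 * counts$tn / (counts$fp + counts$tn), 2), 94.34)
  expect_equal(round(100 * (counts$tp + counts$tn) /
                       do.call(sum, counts), 2), 83.58)

  set.seed(203)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    cases <- data.frame(day = runif(n, 5, 80), t5 = rnorm(n, 0, 5),
                        label = rbinom(n, 1, 0.3))
    cf <- onset_coefficients(rnorm(1), rnorm(1, 0, 0.05), rnorm(1, 0, 0.2))
    ct <- classification_table(cf, cases)
    p <- onset_probability(cf, cases$day, cases$t5)
    tp <- sum(p > 0.5 & cases$label == 1); fn <- sum(p <= 0.5 & cases$label == 1)
    fp <- sum(p > 0.5 & cases$label == 0); tn <- sum(p <= 0.5 & cases$label == 0)
    expect_equal(c(ct$tp, ct$fn, ct$fp, ct$tn), c(tp, fn, fp, tn))
    expect_equal(ct$pct_overall, 100 * (tp + tn) / n)
  }
  expect_error(classification_table(krakow_coefficients("Alnus"),
                                    data.frame(day = numeric(), t5 = numeric(),
                                               label = integer())),
               "no cases")
})
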