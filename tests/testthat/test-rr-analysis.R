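test_that("design matrix loses exactly the incomplete leading lag rows", {
  d <- simulate_daily_series(365, seed = 5)
  des <- build_design(d, "so2", w = 2)
  expect_equal(length(des$y), 364)
  expect_equal(des$n_dropped, 1)
  # intercept + exposure + 6 spline + 6 day-of-week columns
  expect_equal(ncol(des$X), 14)
  expect_equal(nrow(des$X), 364)
})

test_that("constant temperature flags a rank-deficient spline basis", {
  d <- simulate_daily_series(120, seed = 6)
  d$tmin <- 10
  expect_warning(des <- build_design(d, "so2", w = 1), "rank-deficient")
  expect_false(any(grepl("ns_tmin", colnames(des$X))))
})

test_that("female-cold subgroup restricts rows and swaps the response", {
  d <- simulate_daily_series(365, seed = 7)
  des <- build_design(d, "so2", w = 2, sex = "female", season = "cold")
  months <- as.integer(format(des$date, "%m"))
  expect_true(all(months %in% c(10:12, 1:3)))
  expect_equal(des$y,
               d$admissions_female[match(des$date, d$date)])
})

test_that("intercept-only Poisson fit recovers log of the sample mean", {
  withr::local_seed(8)
  y <- rpois(500, 4)
  fit <- fit_poisson(y, matrix(1, length(y), 1,
                               dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit$coefficients), log(mean(y)), tolerance = 1e-7)
})

test_that("an all-zero exposure column is inestimable and errors", {
  withr::local_seed(9)
  y <- rpois(100, 4)
  X <- cbind(`(Intercept)` = rep(1, 100), exposure = rep(0, 100))
  expect_error(fit_poisson(y, X), class = "airadmit_fit_error")
})

test_that("fit_poisson recovers a known coefficient on large samples", {
  withr::local_seed(10)
  n <- 20000
  x <- rnorm(n, 0, 2)
  beta <- 0.15
  y <- rpois(n, exp(1 + beta * x))
  fit <- fit_poisson(y, cbind(`(Intercept)` = 1, exposure = x))
  se <- sqrt(fit$vcov["exposure", "exposure"])
  expect_lt(abs(fit$coefficients["exposure"] - beta), 3 * se)
})

test_that("percent increase transform matches its closed form and inverts", {
  expect_equal(percent_increase(0, 0)$estimate, 0)
  p <- percent_increase(0.01, 0)
  expect_equal(p$estimate, (exp(0.1) - 1) * 100, tolerance = 1e-12)
  expect_equal(p$estimate, 10.5170918, tolerance = 1e-6)
  expect_equal(p$ci_low, p$estimate)

  # strictly increasing in beta and exactly invertible
  betas <- seq(-0.05, 0.05, by = 0.01)
  est <- percent_increase(betas, rep(0.001, length(betas)))$estimate
  expect_true(all(diff(est) > 0))
  back <- log(est / 100 + 1) / 10
  expect_equal(back, betas, tolerance = 1e-12)
})

test_that("rr fit recovers the generator effect within 3 SE", {
  beta_true <- log(1.10) / 10
  d <- simulate_daily_series(4000, beta = beta_true, exposure_window = 2,
                             seed = 12)
  fit <- fit_rr(d, "so2", w = 2)
  expect_lt(abs(fit$beta - beta_true), 3 * fit$se)
  g <- glance(fit)
  expect_true(g$ci_low <= g$percent_increase &
                g$percent_increase <= g$ci_high)
  expect_gt(g$percent_increase, -100)
  td <- tidy(fit)
  expect_true("exposure" %in% td$term)
  expect_equal(nrow(td), 14)
})

test_that("shifting temperature leaves the exposure coefficient unchanged", {
  d <- simulate_daily_series(365, seed = 13)
  f1 <- fit_rr(d, "so2", w = 2)
  d2 <- d
  d2$tmin <- d2$tmin + 5
  f2 <- fit_rr(d2, "so2", w = 2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("lag scan attenuates below the true window and peaks at or above it", {
  # With serially independent exposure days, windows shorter than the true
  # one attenuate the effect (projection slope w/w_true < 1) while longer
  # windows keep its full size, so the best lag lands at or beyond w_true
  # and never below it.
  d <- simulate_daily_series(3000, beta = log(1.30) / 10,
                             exposure_window = 3, seed = 14)
  scan <- lag_scan(d, "so2")
  expect_equal(nrow(scan), 6)
  expect_equal(sum(scan$best), 1)
  best_w <- which(scan$best)
  expect_gte(best_w, 3)
  expect_true(all(scan$percent_increase[1:2] <
                    scan$percent_increase[best_w]))
  expect_true(scan$significant[scan$best])
  # the flag marks exactly the maximal point estimate
  expect_equal(best_w, which.max(scan$percent_increase))
  plt <- autoplot(scan)
  expect_s3_class(plt, "ggplot")
})

test_that("quasi-Poisson widens (or keeps) the Wald interval", {
  d <- simulate_daily_series(365, seed = 15)
  f_pois <- fit_rr(d, "so2", w = 2)
  f_quasi <- fit_rr(d, "so2", w = 2, dispersion = "quasipoisson")
  expect_equal(f_pois$beta, f_quasi$beta, tolerance = 1e-10)
  expect_true(f_quasi$se > 0)
})
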