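test_that("pollution generator degenerates to the means when sds are zero", {
  p <- simulate_pollution(10, sds = c(pm25 = 0, pm10 = 0, so2 = 0, no2 = 0),
                          seed = 1)
  expect_equal(unique(p$pm25), 72)
  expect_equal(unique(p$so2), 17)
  expect_equal(nrow(p), 10)
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(simulate_pollution(100, seed = 11),
                   simulate_pollution(100, seed = 11))
  expect_identical(simulate_tmin(100, seed = 11),
                   simulate_tmin(100, seed = 11))
  expect_identical(
    simulate_state_chain(500, REF_SEVERE_ALL, REF_MILD_ALL, seed = 11),
    simulate_state_chain(500, REF_SEVERE_ALL, REF_MILD_ALL, seed = 11))
  expect_identical(simulate_daily_series(60, seed = 11),
                   simulate_daily_series(60, seed = 11))
})

test_that("copula induces the target Pearson correlation on the data scale", {
  p <- simulate_pollution(50000, seed = 21)
  expect_lt(abs(cor(p$pm25, p$pm10) - 0.86), 0.01)
})

test_that("pollutant marginals hit the study-setting means at n = 365", {
  p <- simulate_pollution(365, seed = 31)
  pp <- pollutant_params()
  for (i in seq_len(nrow(pp))) {
    se <- pp$sd[i] / sqrt(365)
    expect_lt(abs(mean(p[[pp$pollutant[i]]]) - pp$mean[i]), 3 * se)
  }
})

test_that("non-positive-definite correlation targets are rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(
    simulate_pollution(10, means = c(pm25 = 72, pm10 = 116, so2 = 17),
                       sds = c(52, 72, 10), corr = bad),
    class = "airadmit_spec_error")
})

test_that("temperature defaults span roughly -2 to 24 degrees over a year", {
  t <- simulate_tmin(365, seed = 41)
  # realised extremes of the cycle-plus-noise model: near the target range
  # -2..24, with the noise maximum biasing both tails slightly outward
  expect_gt(min(t), -5)
  expect_lt(min(t), 1.5)
  expect_gt(max(t), 22.5)
  expect_lt(max(t), 28)
  expect_lt(abs(mean(t) - 13), 1)
  expect_lt(abs(sd(t) - 7), 0.7)
  t0 <- simulate_tmin(50, amplitude = 0, noise_sd = 0)
  expect_equal(unique(t0), 13)
})

test_that("null-effect admissions match the target daily mean", {
  n <- 20000
  adm <- simulate_admissions(exposure = rep(0, n), tmin = rep(10, n),
                             beta = 0, temp_effect = NULL,
                             dow_effects = NULL, seed = 51)
  se <- sqrt(4.29 / n)
  expect_lt(abs(mean(adm$admissions_total) - 4.29), 3 * se)
  truth <- attr(adm, "truth")
  expect_equal(truth$percent_increase_per10, 0)
})

test_that("degenerate admission specs are rejected", {
  expect_error(simulate_admissions(0, 10, mean_admissions = 0),
               class = "airadmit_spec_error")
  expect_error(simulate_admissions(0, 10, beta = Inf),
               class = "airadmit_spec_error")
})

test_that("composed daily series carries its ground truth and sex split", {
  d <- simulate_daily_series(365, seed = 61)
  truth <- attr(d, "truth")
  expect_equal(truth$pollutant, "so2")
  expect_equal(truth$percent_increase_per10, 7.27, tolerance = 1e-6)
  expect_true(all(d$admissions_male + d$admissions_female ==
                    d$admissions_total))
  expect_silent(validate_daily_series(d))
  # binomial split: female share near 0.61
  expect_lt(abs(sum(d$admissions_female) / sum(d$admissions_total) - 0.61),
            0.05)
})

test_that("state chains honour degenerate transition matrices", {
  ident <- diag(2)
  ch <- simulate_state_chain(50, ident, severity = rep(1L, 50), init = 2,
                             seed = 71)
  expect_true(all(ch$state == 2))

  flip <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  ch2 <- simulate_state_chain(20, flip, severity = rep(1L, 20), seed = 71)
  expect_equal(ch2$state, rep(c(1L, 2L), 10))

  expect_error(simulate_state_chain(10, matrix(c(0.5, 0.6, 0.5, 0.5), 2)),
               class = "airadmit_spec_error")
})

test_that("long-run chain frequencies converge to the generating matrix", {
  n <- 200000
  ch <- ref_chain(n, REF_SEVERE_ALL, "severe", seed = 81)
  from <- ch$state[-n]
  to <- ch$state[-1]
  for (i in 1:2) for (j in 1:2) {
    emp <- sum(from == i & to == j) / sum(from == i)
    expect_lt(abs(emp - REF_SEVERE_ALL[i, j]), 0.005)
  }
})

test_that("odds-ratio day generator reproduces its design parameters", {
  d <- simulate_or_data(50000, odds_ratio = 4, p_exposure = 0.3, p0 = 0.25,
                        seed = 91)
  expect_lt(abs(mean(d$exposed) - 0.3), 0.01)
  expect_lt(abs(mean(d$high[!d$exposed]) - 0.25), 0.01)
})
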