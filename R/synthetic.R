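#' Study-setting pollutant marginals
#'
#' Default per-pollutant daily-mean concentration means and standard
#' deviations (ug/m3) used by the synthetic generator, calibrated to a
#' one-year city-region series: PM2.5 72 (52), PM10 116 (72), SO2 17 (10),
#' NO2 52 (16).
#'
#' @return A tibble with columns `pollutant`, `mean`, `sd`.
#' @export
pollutant_params <- function() {
  tibble(
    pollutant = pollutant_cols(),
    mean = c(72, 116, 17, 52),
    sd = c(52, 72, 10, 16)
  )
}

#' Study-setting inter-pollutant correlation matrix
#'
#' Default 4x4 Pearson correlation target between the daily pollutant
#' concentrations (order pm25, pm10, so2, no2).
#'
#' @return A symmetric positive-definite correlation matrix.
#' @export
default_pollutant_corr <- function() {
  r <- matrix(c(
    1, 0.86, 0.51, 0.55,
    0.86, 1, 0.53, 0.56,
    0.51, 0.53, 1, 0.47,
    0.55, 0.56, 0.47, 1
  ), 4, 4, dimnames = list(pollutant_cols(), pollutant_cols()))
  r
}

# Latent Gaussian correlation inducing Pearson r between two lognormals with
# log-scale sds s1, s2 (exact moment inversion; NA when target unattainable).
latent_corr <- function(r, s1, s2) {
  arg <- 1 + r * sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))
  if (arg <= 0) return(NA_real_)
  log(arg) / (s1 * s2)
}

#' Simulate correlated daily pollutant concentrations
#'
#' Draws strictly positive daily concentrations from lognormal marginals
#' moment-matched to the requested means and SDs, coupled through a Gaussian
#' copula. The latent Gaussian correlation is chosen by exact inversion so
#' that the *induced* Pearson correlation between the lognormal draws matches
#' the target matrix (for lognormal marginals this matching is closed form).
#'
#' @param n_days Number of days to simulate.
#' @param means,sds Named or positional numeric vectors of target means and
#'   SDs (ug/m3), one per pollutant; defaults from [pollutant_params()].
#' @param corr Target Pearson correlation matrix (unit diagonal, symmetric
#'   positive definite); default [default_pollutant_corr()].
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#'
#' @return A tibble with one column per pollutant and `n_days` rows.
#' @export
simulate_pollution <- function(n_days, means = NULL, sds = NULL, corr = NULL,
                               seed = NULL) {
  pp <- pollutant_params()
  if (is.null(means)) means <- setNames(pp$mean, pp$pollutant)
  if (is.null(sds)) sds <- setNames(pp$sd, pp$pollutant)
  if (is.null(corr)) corr <- default_pollutant_corr()
  k <- length(means)
  if (is.null(names(means))) names(means) <- pollutant_cols()[seq_len(k)]
  stopifnot(length(sds) == k, nrow(corr) == k)
  if (any(means <= 0) || any(sds < 0)) {
    abort("means must be positive and sds nonnegative",
          class = "airadmit_spec_error")
  }
  if (max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8)) {
    abort("corr must be symmetric with unit diagonal",
          class = "airadmit_spec_error")
  }
  # Degenerate limit: zero spread collapses to the means.
  if (all(sds == 0)) {
    out <- purrr::map(seq_len(k), ~ rep(means[.x], n_days))
    names(out) <- names(means)
    return(as_tibble(out))
  }
  sig2 <- log(1 + (sds / means)^2)   # log-scale variances
  sig <- sqrt(sig2)
  mu <- log(means) - sig2 / 2
  z_corr <- diag(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) z_corr[i, j] <- latent_corr(corr[i, j], sig[i], sig[j])
  }
  if (anyNA(z_corr)) {
    abort("target correlation unattainable for these marginals",
          class = "airadmit_spec_error")
  }
  ev <- eigen(z_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("correlation matrix is not positive definite on the latent scale",
          class = "airadmit_spec_error")
  }
  draw <- function() {
    z <- MASS::mvrnorm(n_days, mu = rep(0, k), Sigma = z_corr)
    if (n_days == 1) z <- matrix(z, nrow = 1)
    x <- exp(sweep(sweep(z, 2, sig, `*`), 2, mu, `+`))
    # sd = 0 for an individual pollutant degenerates to its mean
    x[, sig == 0] <- matrix(rep(means[sig == 0], each = n_days), nrow = n_days)
    colnames(x) <- names(means)
    as_tibble(x)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate daily minimum temperature
#'
#' A sinusoidal annual cycle (coldest in mid-January) plus iid Gaussian
#' noise. Defaults reproduce the study setting: mean 13 deg C, annual
#' amplitude 10, noise SD 1.2, giving a realised range of about -2 to 24
#' deg C over a year.
#'
#' @param n_days Number of days.
#' @param mean_level Annual mean (deg C).
#' @param amplitude Half-range of the annual cycle (deg C).
#' @param noise_sd SD of day-to-day Gaussian noise (deg C).
#' @param start_date Date of the first day (fixes the phase of the cycle).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Numeric vector of length `n_days`.
#' @export
simulate_tmin <- function(n_days, mean_level = 13, amplitude = 10,
                          noise_sd = 1.2, start_date = as.Date("2014-01-01"),
                          seed = NULL) {
  stopifnot(n_days >= 1)
  doy <- as.integer(format(start_date + seq_len(n_days) - 1, "%j"))
  cycle <- mean_level - amplitude * cos(2 * pi * (doy - 15) / 365.25)
  draw <- function() cycle + rnorm(n_days, 0, noise_sd)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

default_temp_effect <- function(t) 0.02 * ((t - 20) / 10)^2

default_dow_effects <- function() {
  c(Tue = 0.03, Wed = 0.02, Thu = 0, Fri = -0.01, Sat = 0.01, Sun = -0.02)
}

#' Simulate daily admission counts from a log-linear Poisson model
#'
#' Counts are drawn from `Poisson(mu_t)` with
#' `log mu_t = intercept + beta * exposure_t + f(tmin_t) + dow_t`. The
#' intercept is calibrated so that the *marginal* expected daily count equals
#' `mean_admissions` given the realised covariates, which keeps the generator
#' anchored to the study setting (about 4.29 elderly admissions/day)
#' regardless of the effect sizes chosen.
#'
#' @param exposure Numeric exposure series (e.g. a pollutant concentration or
#'   a lag-window moving average of one); `NA`s yield `NA` counts.
#' @param tmin Daily minimum temperature series, same length.
#' @param beta True log-rate coefficient per unit exposure (per ug/m3).
#' @param mean_admissions Target marginal mean daily count.
#' @param temp_effect Function of `tmin` giving its log-scale contribution;
#'   the default is a mild convex effect rising toward cold days. Use
#'   `function(t) 0` to switch it off.
#' @param dow_effects Named numeric vector of 6 log-scale day-of-week
#'   contrasts relative to Monday (`Tue` .. `Sun`); default small effects,
#'   `NULL` for none.
#' @param start_date Date of the first day (fixes weekday alignment).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `date`, `admissions_total`, `log_mu`, plus a
#'   `truth` attribute recording `intercept`, `beta`, the true percent
#'   increase per 10 ug/m3 and the effect functions used.
#' @export
simulate_admissions <- function(exposure, tmin, beta = 0,
                                mean_admissions = 4.29,
                                temp_effect = default_temp_effect,
                                dow_effects = default_dow_effects(),
                                start_date = as.Date("2014-01-01"),
                                seed = NULL) {
  n <- length(exposure)
  stopifnot(length(tmin) == n)
  if (!is.finite(mean_admissions) || mean_admissions <= 0) {
    abort("mean_admissions must be finite and positive",
          class = "airadmit_spec_error")
  }
  if (!is.finite(beta)) {
    abort("beta must be finite", class = "airadmit_spec_error")
  }
  date <- start_date + seq_len(n) - 1
  if (is.null(temp_effect)) temp_effect <- function(t) rep(0, length(t))
  dow_term <- rep(0, n)
  if (!is.null(dow_effects)) {
    stopifnot(length(dow_effects) == 6)
    wd <- as.integer(format(date, "%u"))  # 1 = Monday, locale-independent
    dow_term <- c(0, unname(dow_effects))[wd]
  }
  eta0 <- beta * exposure + temp_effect(tmin) + dow_term
  ok <- is.finite(eta0)
  if (!any(ok)) {
    abort("no finite log-mean values", class = "airadmit_spec_error")
  }
  intercept <- log(mean_admissions) - log(mean(exp(eta0[ok])))
  if (!is.finite(intercept)) {
    abort("non-finite log-mean: check beta and effect functions",
          class = "airadmit_spec_error")
  }
  log_mu <- intercept + eta0
  draw <- function() {
    y <- rep(NA_integer_, n)
    y[ok] <- rpois(sum(ok), exp(log_mu[ok]))
    y
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble(date = date, admissions_total = counts, log_mu = log_mu)
  attr(out, "truth") <- list(
    intercept = intercept, beta = beta,
    percent_increase_per10 = (exp(10 * beta) - 1) * 100,
    mean_admissions = mean_admissions,
    temp_effect = temp_effect, dow_effects = dow_effects
  )
  out
}

#' Simulate a full daily series with known ground truth
#'
#' Composes [simulate_pollution()], [simulate_tmin()] and
#' [simulate_admissions()] into a standard daily-series tibble. The exposure
#' driving admissions is the `exposure_window`-day moving average of the
#' chosen pollutant, so a lag-window regression at that window is correctly
#' specified. Sex-specific counts are a binomial split of the total (female
#' share 0.61, the study's composition).
#'
#' @param n_days Number of days (default one year).
#' @param pollutant Which pollutant drives admissions (default `"so2"`).
#' @param beta True log-rate coefficient per ug/m3 of the lagged exposure.
#' @param exposure_window Moving-average window (days) of the true exposure.
#' @param mean_admissions Target marginal mean daily admissions.
#' @param female_share Expected share of female admissions.
#' @param start_date First calendar day.
#' @param means,sds,corr Passed to [simulate_pollution()].
#' @param temp_effect,dow_effects Passed to [simulate_admissions()].
#' @param seed Optional integer seed covering the whole composition.
#'
#' @return A daily-series tibble (`date`, `admissions_total`,
#'   `admissions_male`, `admissions_female`, `pm25`, `pm10`, `so2`, `no2`,
#'   `tmin`) with a `truth` attribute (generator parameters, true percent
#'   increase per 10 ug/m3, exposure definition).
#' @export
simulate_daily_series <- function(n_days = 365, pollutant = "so2",
                                  beta = log(1.0727) / 10,
                                  exposure_window = 2,
                                  mean_admissions = 4.29,
                                  female_share = 0.61,
                                  start_date = as.Date("2014-01-01"),
                                  means = NULL, sds = NULL, corr = NULL,
                                  temp_effect = default_temp_effect,
                                  dow_effects = default_dow_effects(),
                                  seed = NULL) {
  build <- function() {
    # lead-in days so the first analysis day has a full exposure window
    lead <- exposure_window - 1
    pol <- simulate_pollution(n_days + lead, means = means, sds = sds,
                              corr = corr)
    tmin_full <- simulate_tmin(n_days + lead,
                               start_date = start_date - lead)
    expo_full <- moving_average(pol[[pollutant]], exposure_window)
    keep <- seq.int(lead + 1, n_days + lead)
    adm <- simulate_admissions(expo_full[keep], tmin_full[keep], beta = beta,
                               mean_admissions = mean_admissions,
                               temp_effect = temp_effect,
                               dow_effects = dow_effects,
                               start_date = start_date)
    female <- rbinom(n_days, adm$admissions_total, female_share)
    out <- tibble(
      date = adm$date,
      admissions_total = adm$admissions_total,
      admissions_male = adm$admissions_total - female,
      admissions_female = female
    )
    out <- dplyr::bind_cols(out, pol[keep, ], tibble(tmin = tmin_full[keep]))
    attr(out, "truth") <- c(attr(adm, "truth"),
                            list(pollutant = pollutant,
                                 exposure_window = exposure_window,
                                 female_share = female_share))
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a severity-stratified two-state chain
#'
#' Generates a binary pollution-severity series and a daily admission-state
#' chain (1 = low, 2 = high) in which the transition from day `t` to `t + 1`
#' is governed by the severity stratum attributed to the pair. Under the
#' default destination-day convention the matrix acting on pair `(t, t+1)`
#' is selected by `severity[t + 1]`, matching the idea that an exceedance
#' window ending on a day drives that day's admissions.
#'
#' @param n_days Chain length.
#' @param p_severe_matrix 2x2 row-stochastic transition matrix used on severe
#'   days (rows: from-state 1, 2).
#' @param p_mild_matrix Matrix used on mild days; defaults to
#'   `p_severe_matrix` (single regime).
#' @param severity Optional explicit binary severity series (0/1, logical, or
#'   `"mild"`/`"severe"`); when `NULL`, iid Bernoulli(`p_severe`) days.
#' @param p_severe Probability a day is severe when `severity` is `NULL`.
#' @param init Initial state (1 or 2).
#' @param attribution `"destination"` (default) or `"origin"`: which day's
#'   severity governs the pair `(t, t + 1)`.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `day`, `severity` (factor mild/severe) and
#'   `state` (integer 1/2).
#' @export
simulate_state_chain <- function(n_days, p_severe_matrix,
                                 p_mild_matrix = NULL,
                                 severity = NULL, p_severe = 0.3, init = 1,
                                 attribution = c("destination", "origin"),
                                 seed = NULL) {
  attribution <- match.arg(attribution)
  check_tpm <- function(p, label) {
    if (!is.matrix(p) || any(dim(p) != 2) || any(p < 0) || any(p > 1) ||
        max(abs(rowSums(p) - 1)) > 1e-8) {
      abort(paste0(label, " must be a 2x2 row-stochastic matrix"),
            class = "airadmit_spec_error")
    }
  }
  check_tpm(p_severe_matrix, "p_severe_matrix")
  if (is.null(p_mild_matrix)) p_mild_matrix <- p_severe_matrix
  check_tpm(p_mild_matrix, "p_mild_matrix")
  stopifnot(init %in% c(1, 2), n_days >= 2)
  build <- function() {
    sev <- severity
    if (is.null(sev)) {
      sev <- rbinom(n_days, 1, p_severe)
    } else {
      sev <- coerce_severity_binary(sev)
      stopifnot(length(sev) == n_days)
    }
    state <- integer(n_days)
    state[1] <- init
    u <- runif(n_days)
    # row 1->2 and row 2->2 probabilities per regime, indexed by severity
    p12 <- ifelse(sev == 1, p_severe_matrix[1, 2], p_mild_matrix[1, 2])
    p22 <- ifelse(sev == 1, p_severe_matrix[2, 2], p_mild_matrix[2, 2])
    for (t in 2:n_days) {
      g <- if (attribution == "destination") t else t - 1L
      p_high <- if (state[t - 1] == 1) p12[g] else p22[g]
      state[t] <- if (u[t] < p_high) 2L else 1L
    }
    tibble(day = seq_len(n_days),
           severity = factor(ifelse(sev == 1, "severe", "mild"),
                             levels = c("mild", "severe")),
           state = state)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Map logical / 0-1 / mild-severe codings to integer 0 (mild) / 1 (severe),
# preserving NA.
coerce_severity_binary <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !x %in% c("mild", "severe") & !is.na(x)
    if (any(bad)) abort("severity labels must be 'mild'/'severe'",
                        class = "airadmit_spec_error")
    return(ifelse(x == "severe", 1L, 0L))
  }
  if (is.logical(x)) return(as.integer(x))
  if (!all(x %in% c(0, 1) | is.na(x))) {
    abort("numeric severity must be 0 (mild) / 1 (severe)",
          class = "airadmit_spec_error")
  }
  as.integer(x)
}

#' Simulate exposure/outcome days with a known odds ratio
#'
#' Draws `n` independent days with binary exposure (prevalence `p_exposure`)
#' and a binary high-day outcome from a logistic mechanism whose true odds
#' ratio is `odds_ratio` against baseline outcome probability `p0`.
#'
#' @param n Number of days.
#' @param odds_ratio True exposure odds ratio.
#' @param p_exposure Exposure prevalence.
#' @param p0 Outcome probability on unexposed days.
#' @param seed Optional integer seed.
#' @return A tibble with logical columns `exposed` and `high`.
#' @export
simulate_or_data <- function(n, odds_ratio, p_exposure = 0.3, p0 = 0.25,
                             seed = NULL) {
  stopifnot(odds_ratio > 0, p_exposure > 0, p_exposure < 1, p0 > 0, p0 < 1)
  odds1 <- odds_ratio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  draw <- function() {
    exposed <- runif(n) < p_exposure
    high <- runif(n) < ifelse(exposed, p1, p0)
    tibble(exposed = exposed, high = high)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
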