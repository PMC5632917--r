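subgroup_response <- function(data, sex) {
  col <- switch(sex,
    all = "admissions_total",
    male = "admissions_male",
    female = "admissions_female"
  )
  if (!col %in% names(data)) {
    abort(paste0("subgroup '", sex, "' needs column '", col, "'"),
          class = "airadmit_schema_error")
  }
  col
}

#' Build the single-pollutant regression design
#'
#' Assembles the response and covariate matrix for one Poisson regression:
#' the lag-window moving average of one pollutant, a natural cubic spline
#' basis of daily minimum temperature (interior knots at equally spaced
#' quantiles, natural boundary constraints), and six day-of-week indicators
#' (Monday reference). Lag features are computed on the *full* series before
#' any subgroup filtering so that season subgroups keep valid exposure
#' windows; rows with any missing value are dropped listwise.
#'
#' @param data A validated daily-series tibble.
#' @param pollutant One of `"pm25"`, `"pm10"`, `"so2"`, `"no2"`.
#' @param w Lag window in days (1..6), see [moving_average()].
#' @param df Degrees of freedom of the temperature spline (default 6).
#' @param sex Subgroup response: `"all"`, `"male"`, `"female"`.
#' @param season Subgroup filter: `"both"`, `"warm"`, `"cold"`.
#'
#' @return A list with `y` (counts), `X` (covariate matrix including an
#'   intercept column), `date`, `n_dropped` (rows lost to missingness) and
#'   the subgroup description.
#' @export
build_design <- function(data, pollutant, w = 1, df = 6,
                         sex = c("all", "male", "female"),
                         season = c("both", "warm", "cold")) {
  sex <- match.arg(sex)
  season <- match.arg(season)
  if (df < 3) abort("spline df must be >= 3", class = "airadmit_spec_error")
  if (!pollutant %in% names(data)) {
    abort(paste0("pollutant column '", pollutant, "' missing"),
          class = "airadmit_schema_error")
  }
  ycol <- subgroup_response(data, sex)
  expo <- moving_average(data[[pollutant]], w)
  keep_season <- if (season == "both") rep(TRUE, nrow(data)) else
    season_of(data$date) == season
  sub <- tibble(date = data$date, y = data[[ycol]], exposure = expo,
                tmin = data$tmin)[keep_season, ]
  complete <- complete.cases(sub)
  n_dropped <- sum(!complete)
  sub <- sub[complete, ]
  if (nrow(sub) < 30) {
    abort(paste0("subgroup has only ", nrow(sub), " usable days (< 30)"),
          class = "airadmit_validation_error")
  }
  spline_basis <- NULL
  if (sd(sub$tmin) == 0) {
    warn("tmin is constant: spline basis is rank-deficient and is omitted")
  } else {
    spline_basis <- splines::ns(sub$tmin, df = df)
    colnames(spline_basis) <- paste0("ns_tmin", seq_len(ncol(spline_basis)))
  }
  wd <- factor(as.integer(format(sub$date, "%u")), levels = 1:7,
               labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  dow <- model.matrix(~ wd)[, -1, drop = FALSE]
  colnames(dow) <- paste0("dow", levels(wd)[-1])
  X <- cbind(`(Intercept)` = 1, exposure = sub$exposure, spline_basis, dow)
  if (nrow(X) < ncol(X)) {
    abort("fewer usable rows than design columns",
          class = "airadmit_validation_error")
  }
  list(y = sub$y, X = X, date = sub$date, n_dropped = n_dropped,
       pollutant = pollutant, w = as.integer(w), sex = sex, season = season)
}

#' Fit a Poisson regression by maximum likelihood
#'
#' Thin wrapper around [stats::glm()] (iteratively reweighted least squares,
#' convergence tolerance 1e-8) taking an explicit response and covariate
#' matrix. A quasi-Poisson option rescales the covariance by the Pearson
#' dispersion for overdispersed series.
#'
#' @param y Integer response counts.
#' @param X Covariate matrix (include an intercept column if wanted).
#' @param dispersion `"poisson"` (default) or `"quasipoisson"`.
#' @param maxit Maximum IRLS iterations.
#' @return A list with `coefficients`, `vcov`, `converged`, `iterations`,
#'   `deviance`, `dispersion` and the underlying `glm` object (`fit`).
#' @export
fit_poisson <- function(y, X, dispersion = c("poisson", "quasipoisson"),
                        maxit = 100) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(y) == nrow(X))
  fam <- if (dispersion == "poisson") poisson() else quasipoisson()
  dat <- as.data.frame(X, check.names = FALSE)
  dat$.y <- y
  form <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y",
                             intercept = FALSE)
  fit <- glm(form, data = dat, family = fam,
             control = glm.control(epsilon = 1e-8, maxit = maxit))
  if (!fit$converged) {
    abort(paste0("IRLS did not converge in ", fit$iter, " iterations"),
          class = "airadmit_fit_error")
  }
  cf <- coef(fit)
  names(cf) <- colnames(X)
  if (anyNA(cf)) {
    abort(paste0("aliased (inestimable) coefficient(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "airadmit_fit_error")
  }
  vc <- vcov(fit)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = cf, vcov = vc, converged = fit$converged,
       iterations = fit$iter, deviance = fit$deviance,
       dispersion = dispersion, fit = fit)
}

#' Percent increase per 10 ug/m3 from a log-rate coefficient
#'
#' Transforms a Poisson log-rate coefficient (per unit concentration) and its
#' standard error into the percent change in daily admissions for a
#' `per`-unit increase, with a Wald 95% confidence interval:
#' point `(exp(per * beta) - 1) * 100`, CI from `beta +/- 1.96 * se`.
#'
#' @param beta Log-rate coefficient(s) per ug/m3.
#' @param se Standard error(s).
#' @param per Concentration increment (default 10 ug/m3).
#' @return A tibble with `estimate`, `ci_low`, `ci_high` (percent).
#' @export
percent_increase <- function(beta, se, per = 10) {
  stopifnot(all(is.finite(beta)), all(is.finite(se)), all(se >= 0))
  tibble(
    estimate = (exp(per * beta) - 1) * 100,
    ci_low = (exp(per * (beta - 1.96 * se)) - 1) * 100,
    ci_high = (exp(per * (beta + 1.96 * se)) - 1) * 100
  )
}

#' Fit one pollutant x lag x subgroup relative-risk model
#'
#' Builds the design with [build_design()], fits the Poisson GLM and reports
#' the exposure effect as percent increase per 10 ug/m3.
#'
#' @inheritParams build_design
#' @inheritParams fit_poisson
#' @return An object of class `rr_fit`: the fitted model plus the headline
#'   effect estimate. Use [tidy()] for coefficients, [glance()] for the
#'   one-row summary.
#' @export
fit_rr <- function(data, pollutant, w = 1, df = 6,
                   sex = c("all", "male", "female"),
                   season = c("both", "warm", "cold"),
                   dispersion = c("poisson", "quasipoisson")) {
  design <- build_design(data, pollutant, w = w, df = df,
                         sex = sex, season = season)
  fit <- fit_poisson(design$y, design$X, dispersion = dispersion)
  beta <- unname(fit$coefficients["exposure"])
  se <- sqrt(fit$vcov["exposure", "exposure"])
  pct <- percent_increase(beta, se)
  structure(list(
    pollutant = design$pollutant, w = design$w,
    lag = lag_label(design$w), sex = design$sex, season = design$season,
    beta = beta, se = se,
    p_value = 2 * pnorm(-abs(beta / se)),
    percent_increase = pct$estimate,
    ci_low = pct$ci_low, ci_high = pct$ci_high,
    n_days = length(design$y), n_dropped = design$n_dropped,
    model = fit
  ), class = "rr_fit")
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson RR fit: %s %s (%s, %s season), n = %d days\n", x$pollutant,
    x$lag, x$sex, x$season, x$n_days))
  cat(sprintf(
    "  percent increase per 10 ug/m3: %.2f (95%% CI %.2f, %.2f), p = %.4g\n",
    x$percent_increase, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @rdname fit_rr
#' @param x An `rr_fit` object.
#' @param ... Unused.
#' @export
tidy.rr_fit <- function(x, ...) {
  cf <- x$model$coefficients
  se <- sqrt(diag(x$model$vcov))
  tibble(
    term = names(cf), estimate = unname(cf), std.error = unname(se),
    statistic = unname(cf / se),
    p.value = 2 * pnorm(-abs(unname(cf / se)))
  )
}

#' @rdname fit_rr
#' @export
glance.rr_fit <- function(x, ...) {
  tibble(
    pollutant = x$pollutant, lag = x$lag, sex = x$sex, season = x$season,
    beta = x$beta, se = x$se, percent_increase = x$percent_increase,
    ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
    significant = x$ci_low > 0 | x$ci_high < 0,
    n_days = x$n_days, deviance = x$model$deviance
  )
}

#' Scan lag windows for one pollutant and subgroup
#'
#' Fits the single-pollutant model at every lag window (default lag0 through
#' lag0-5) and flags the best lag: the window with the maximal percent
#' increase point estimate. Significance is a two-sided Wald test at the 5%
#' level (CI excluding 0).
#'
#' @inheritParams fit_rr
#' @param windows Integer vector of windows to scan (subset of 1..6).
#' @return A tibble of class `lag_scan`, one row per window: effect
#'   estimates, CI, p-value, `significant` and `best` flags.
#' @export
lag_scan <- function(data, pollutant, windows = 1:6, df = 6,
                     sex = c("all", "male", "female"),
                     season = c("both", "warm", "cold"),
                     dispersion = c("poisson", "quasipoisson")) {
  sex <- match.arg(sex)
  season <- match.arg(season)
  rows <- purrr::map_dfr(windows, function(w) {
    glance(fit_rr(data, pollutant, w = w, df = df, sex = sex,
                  season = season, dispersion = dispersion))
  })
  rows <- mutate(rows, best = .data$percent_increase ==
                   max(.data$percent_increase))
  class(rows) <- c("lag_scan", class(rows))
  rows
}

#' @rdname lag_scan
#' @param object A `lag_scan` tibble.
#' @param ... Unused.
#' @export
autoplot.lag_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$lag, levels = .data$lag),
                               y = .data$percent_increase)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high,
                                          colour = .data$significant)) +
    ggplot2::labs(
      x = "lag window",
      y = "percent increase per 10 µg/m³",
      colour = "CI excludes 0",
      title = paste0(unique(object$pollutant), " – admissions (",
                     unique(object$sex), ", ", unique(object$season),
                     " season)")
    ) +
    ggplot2::theme_minimal()
}
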