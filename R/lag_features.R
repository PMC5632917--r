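#' National ambient concentration standards
#'
#' Daily-mean concentration thresholds (ug/m3) of the Chinese national
#' ambient air quality standards used to define exceedance days: primary and
#' secondary standards per pollutant. NO2 has a single (primary) standard.
#'
#' @return A tibble with columns `pollutant`, `standard`
#'   (`"primary"`/`"secondary"`) and `threshold`; rows without a standard are
#'   omitted.
#' @export
pollution_standards <- function() {
  tibble(
    pollutant = rep(pollutant_cols(), each = 2),
    standard = rep(c("primary", "secondary"), 4),
    threshold = c(35, 75, 50, 150, 50, 150, 80, NA)
  ) %>% filter(!is.na(.data$threshold))
}

check_window <- function(w) {
  if (length(w) != 1 || is.na(w) || w != round(w) || w < 1 || w > 6) {
    abort("window w must be a single integer in 1..6 (lag0 .. lag0-5)",
          class = "airadmit_spec_error")
  }
  as.integer(w)
}

#' Lag-window moving average
#'
#' The value at day `t` is the mean of days `t - w + 1 .. t` (the "lag0-(w-1)"
#' exposure metric). The first `w - 1` days, and any day whose window touches
#' a missing value, are `NA`.
#'
#' @param x Numeric concentration series in day order.
#' @param w Window length in days (1..6); `w = 1` is the current-day value.
#' @return Numeric series of the same length.
#' @export
moving_average <- function(x, w) {
  w <- check_window(w)
  if (w == 1) return(as.numeric(x))
  as.numeric(stats::filter(as.numeric(x), rep(1 / w, w), sides = 1))
}

#' Count of threshold exceedances in a trailing window
#'
#' The value at day `t` is the number of days among `t - w + 1 .. t` on which
#' the concentration exceeded `threshold`. Missingness propagates as in
#' [moving_average()].
#'
#' @inheritParams moving_average
#' @param threshold Concentration threshold (ug/m3).
#' @param strict If `TRUE` (default) "exceeds" means strictly greater than
#'   the threshold; `FALSE` uses greater-or-equal.
#' @return Integer-valued numeric series (`NA` where the window is
#'   incomplete).
#' @export
exceedance_count <- function(x, threshold, w, strict = TRUE) {
  w <- check_window(w)
  if (!is.finite(threshold)) {
    abort("threshold must be finite", class = "airadmit_spec_error")
  }
  hit <- if (strict) as.numeric(x > threshold) else as.numeric(x >= threshold)
  if (w == 1) return(hit)
  as.numeric(stats::filter(hit, rep(1, w), sides = 1))
}

#' Binary exceedance index
#'
#' Equals 1 on days where the pollutant exceeded `threshold` on at least `k`
#' of the last `w` days (window ending today), else 0; `NA` while the window
#' is incomplete. This is the binary "severe pollution" indicator scored in
#' the odds-ratio grid search.
#'
#' @inheritParams exceedance_count
#' @param k Minimum number of exceedance days, `1 <= k <= w`.
#' @return Numeric 0/1 series with leading `NA`s.
#' @export
exceedance_index <- function(x, threshold, w, k, strict = TRUE) {
  w <- check_window(w)
  if (length(k) != 1 || is.na(k) || k != round(k) || k < 1 || k > w) {
    abort("k must be a single integer with 1 <= k <= w",
          class = "airadmit_spec_error")
  }
  cnt <- exceedance_count(x, threshold, w, strict = strict)
  as.numeric(cnt >= k)
}

lag_label <- function(w) {
  ifelse(w == 1, "lag0", paste0("lag0-", w - 1))
}
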