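#' Lorenz curve of daily admission counts
#'
#' Sorts the daily counts ascending and accumulates their share of the total:
#' the point `(x_i, L_i)` gives the proportion `L_i` of all admissions
#' contributed by the `x_i = i/N` days with the lowest counts. The curve
#' starts at (0, 0), ends at (1, 1), is nondecreasing, convex and lies below
#' the diagonal.
#'
#' @param counts Nonnegative daily admission counts (not all zero).
#' @return A tibble of class `lorenz_curve` with columns `p_days`,
#'   `p_admissions` (including the origin) and attribute `counts_sorted`.
#' @export
lorenz_curve <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0 || any(counts < 0)) {
    abort("counts must be nonnegative and nonempty",
          class = "airadmit_validation_error")
  }
  if (sum(counts) == 0) {
    abort("all counts are zero: Lorenz curve undefined",
          class = "airadmit_validation_error")
  }
  s <- sort(counts)
  n <- length(s)
  out <- tibble(
    p_days = c(0, seq_len(n) / n),
    p_admissions = c(0, cumsum(s) / sum(s))
  )
  attr(out, "counts_sorted") <- s
  class(out) <- c("lorenz_curve", class(out))
  out
}

#' Gini coefficient implied by a Lorenz curve
#'
#' Trapezoidal area between the diagonal and the curve, scaled to `[0, 1]`.
#'
#' @param curve A `lorenz_curve` object (or raw counts).
#' @return The Gini coefficient.
#' @export
gini_coefficient <- function(curve) {
  if (!inherits(curve, "lorenz_curve")) curve <- lorenz_curve(curve)
  x <- curve$p_days
  y <- curve$p_admissions
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  1 - 2 * auc
}

#' @rdname lorenz_curve
#' @param object A `lorenz_curve` object.
#' @param ... Unused.
#' @export
autoplot.lorenz_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$p_days, .data$p_admissions)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "cumulative proportion of days (sorted by admissions)",
      y = "cumulative proportion of admissions",
      title = sprintf("Lorenz curve of daily admissions (Gini = %.3f)",
                      gini_coefficient(object))
    ) +
    ggplot2::theme_minimal()
}

#' High-day count threshold from the Lorenz tail
#'
#' Finds the admission-count threshold `c` defining "high" days as roughly
#' the top `q` share of days: the smallest observed count value such that the
#' fraction of days with count `>= c` does not exceed `q`. Ties at `c` are
#' all labelled high, so the realised high-day share is the largest share
#' `<= q` achievable at an observed count boundary. If even the maximal
#' count class exceeds `q` (e.g. all counts equal), a warning is issued and
#' the maximum count is returned.
#'
#' @param counts Nonnegative daily admission counts.
#' @param q Target top share of days (default 0.30).
#' @return The integer threshold `c`.
#' @export
high_day_threshold <- function(counts, q = 0.3) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0 || q <= 0 || q >= 1) {
    abort("need nonempty counts and 0 < q < 1",
          class = "airadmit_spec_error")
  }
  n <- length(counts)
  candidates <- sort(unique(counts))
  frac_ge <- vapply(candidates, function(c) mean(counts >= c), numeric(1))
  ok <- which(frac_ge <= q)
  if (length(ok) == 0) {
    warn(paste0("no count class has tail share <= ", q,
                "; using the maximum count (degenerate distribution)"))
    return(max(counts))
  }
  candidates[ok[1]]
}

#' Label daily admission states
#'
#' Deterministic two-state labelling: state 2 ("high day") when the count is
#' at least the threshold `c`, else state 1 ("low day"). Day order is
#' preserved; `NA` counts give `NA` states.
#'
#' @param counts Daily admission counts in day order.
#' @param c Count threshold (see [high_day_threshold()]).
#' @return Integer vector of states (1 low / 2 high).
#' @export
label_states <- function(counts, c) {
  if (length(c) != 1 || is.na(c) || c < 0) {
    abort("threshold c must be a single nonnegative number",
          class = "airadmit_spec_error")
  }
  ifelse(is.na(counts), NA_integer_, ifelse(counts >= c, 2L, 1L))
}

#' Add admission states to a daily series
#'
#' Convenience wrapper: derives the high-day threshold from the chosen
#' response column's own Lorenz tail and appends a `state` column.
#'
#' @param data A daily-series tibble.
#' @param q Target top share of high days.
#' @param response Response column (default total admissions; use the
#'   subgroup column when labelling a subgroup series).
#' @return `data` with an integer `state` column; the threshold is stored in
#'   attribute `state_threshold`.
#' @export
add_states <- function(data, q = 0.3, response = "admissions_total") {
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' missing"),
          class = "airadmit_schema_error")
  }
  thr <- high_day_threshold(data[[response]], q = q)
  out <- mutate(data, state = label_states(.data[[response]], thr))
  attr(out, "state_threshold") <- thr
  out
}
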