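#' 2x2 exposure/state contingency table
#'
#' Cross-tabulates a binary exceedance index against daily admission states,
#' dropping days where either is undefined: `a` = exposed & high, `b` =
#' exposed & low, `c` = unexposed & high, `d` = unexposed & low.
#'
#' @param index Binary (0/1 or logical) severity index series.
#' @param state Integer state series (1 low / 2 high), same length.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(index, state) {
  stopifnot(length(index) == length(state))
  keep <- !is.na(index) & !is.na(state)
  if (sum(keep) < 4) {
    abort("fewer than 4 days with defined index and state",
          class = "airadmit_validation_error")
  }
  e <- as.integer(index[keep]) == 1L
  h <- as.integer(state[keep]) == 2L
  tibble(
    a = sum(e & h), b = sum(e & !h),
    c = sum(!e & h), d = sum(!e & !h),
    n = sum(keep)
  )
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' `OR = (a d) / (b c)` with 95% CI
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the estimate incalculable: the result is flagged `valid = FALSE` with `NA`
#' values (no continuity correction is applied).
#'
#' @param a,b,c,d Cell counts (exposed/high, exposed/low, unexposed/high,
#'   unexposed/low). `a` may also be a one-row table from
#'   [contingency_table()].
#' @return A one-row tibble: `or`, `ci_low`, `ci_high`, `valid` and the
#'   cells.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.data.frame(a)) {
    tab <- a
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  stopifnot(length(a) == 1, !is.null(b), !is.null(c), !is.null(d))
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("cells must be nonnegative counts", class = "airadmit_spec_error")
  }
  if (any(cells == 0)) {
    return(tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  valid = FALSE, a = a, b = b, c = c, d = d))
  }
  or <- (a * d) / (b * c)
  se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(
    or = or,
    ci_low = exp(log(or) - 1.96 * se_log),
    ci_high = exp(log(or) + 1.96 * se_log),
    valid = TRUE, a = a, b = b, c = c, d = d
  )
}

#' Grid search over exceedance-index candidates
#'
#' Evaluates every candidate severity index (pollutant x national standard x
#' window `w` in `windows` x minimum exceedance count `k <= w`) against the
#' daily admission states and scores each by the odds ratio of
#' [contingency_table()]. The selected index is the candidate with the
#' largest valid odds ratio; candidates with `OR <= 1` (protective or null)
#' are never selected. Ties are broken toward the smaller window, then the
#' smaller count (the most parsimonious index).
#'
#' @param data A daily-series tibble with pollutant columns.
#' @param state Integer state series aligned with `data` (1 low / 2 high).
#' @param standards Threshold registry tibble (`pollutant`, `standard`,
#'   `threshold`); defaults to the national standards
#'   ([pollution_standards()]).
#' @param windows Candidate windows (default 1..6).
#' @param strict Exceedance convention, see [exceedance_count()].
#' @return A tibble of class `index_grid`: one row per candidate with cells,
#'   `or`, `ci_low`, `ci_high`, `valid` and a `selected` flag.
#' @export
index_grid_search <- function(data, state, standards = pollution_standards(),
                              windows = 1:6, strict = TRUE) {
  stopifnot(nrow(data) == length(state))
  grid <- tidyr::crossing(
    standards,
    w = as.integer(windows)
  ) %>%
    dplyr::filter(.data$pollutant %in% names(data)) %>%
    dplyr::rowwise() %>%
    dplyr::reframe(pollutant = .data$pollutant, standard = .data$standard,
                   threshold = .data$threshold, w = .data$w,
                   k = seq_len(.data$w))
  rows <- purrr::pmap_dfr(grid, function(pollutant, standard, threshold,
                                         w, k) {
    idx <- exceedance_index(data[[pollutant]], threshold, w, k,
                            strict = strict)
    or <- odds_ratio(contingency_table(idx, state))
    dplyr::bind_cols(
      tibble(pollutant = pollutant, standard = standard,
             threshold = threshold, lag = lag_label(w), w = w, k = k),
      or
    )
  })
  eligible <- rows$valid & !is.na(rows$or) & rows$or > 1
  rows$selected <- FALSE
  if (!any(eligible)) {
    abort("no valid candidate index with OR > 1",
          class = "airadmit_selection_error")
  }
  ord <- order(-ifelse(eligible, rows$or, -Inf), rows$w, rows$k)
  rows$selected[ord[1]] <- TRUE
  class(rows) <- c("index_grid", class(rows))
  rows
}

#' Selected candidate of an index grid
#'
#' @param grid An `index_grid` tibble from [index_grid_search()].
#' @return The selected row.
#' @export
selected_index <- function(grid) {
  dplyr::filter(grid, .data$selected)
}

#' Daily severity series from a selected index candidate
#'
#' Applies the exceedance index of a (selected) candidate to the daily
#' series, yielding the binary pollution-severity series used to stratify
#' the Markov transition estimates. Leading days with incomplete windows are
#' `NA`.
#'
#' @param data A daily-series tibble.
#' @param candidate A one-row tibble with `pollutant`, `threshold`, `w`, `k`
#'   (e.g. from [selected_index()]).
#' @param strict Exceedance convention.
#' @return Numeric 0/1 series aligned with `data`.
#' @export
severity_series <- function(data, candidate, strict = TRUE) {
  stopifnot(nrow(candidate) == 1)
  exceedance_index(data[[candidate$pollutant]], candidate$threshold,
                   candidate$w, candidate$k, strict = strict)
}
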