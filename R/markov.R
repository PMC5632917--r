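state_levels <- c("1", "2")

#' Count daily state transitions by severity stratum
#'
#' Tallies consecutive-day pairs `(t, t + 1)` of the two-state admission
#' series into a `2 x 2 x strata` array `n[from, to, stratum]`. Each pair is
#' attributed to the severity value of its destination day `t + 1` (default):
#' the exceedance window ending on a day is taken to drive that day's
#' admissions. Pairs with an undefined state on either day, or an undefined
#' attributed severity, are dropped — so an `NA` inserted between two
#' concatenated segments cleanly separates them.
#'
#' @param state Integer state series (1 low / 2 high), `NA` allowed.
#' @param severity Optional severity series (0/1, logical or
#'   `"mild"`/`"severe"`); `NULL` pools everything into one `"all"` stratum.
#' @param attribution `"destination"` (default) or `"origin"`.
#' @return Integer array `2 x 2 x n_strata` with dimnames `from`, `to`,
#'   `severity`; attribute `n_pairs` gives the usable-pair count.
#' @export
count_transitions <- function(state, severity = NULL,
                              attribution = c("destination", "origin")) {
  attribution <- match.arg(attribution)
  n <- length(state)
  stopifnot(n >= 2)
  state <- as.integer(state)
  if (any(!state %in% c(1L, 2L) & !is.na(state))) {
    abort("states must be 1 (low) or 2 (high)", class = "airadmit_spec_error")
  }
  if (is.null(severity)) {
    sev_lab <- rep("all", n)
    strata <- "all"
  } else {
    stopifnot(length(severity) == n)
    sev01 <- coerce_severity_binary(severity)
    sev_lab <- c("mild", "severe")[sev01 + 1L]
    strata <- c("mild", "severe")
  }
  from <- state[-n]
  to <- state[-1]
  gov <- if (attribution == "destination") sev_lab[-1] else sev_lab[-n]
  keep <- !is.na(from) & !is.na(to) & !is.na(gov)
  if (!any(keep)) {
    abort("no usable consecutive pairs", class = "airadmit_validation_error")
  }
  counts <- array(0L, dim = c(2, 2, length(strata)),
                  dimnames = list(from = state_levels, to = state_levels,
                                  severity = strata))
  tab <- table(factor(from[keep], levels = 1:2),
               factor(to[keep], levels = 1:2),
               factor(gov[keep], levels = strata))
  counts[] <- as.integer(tab)
  attr(counts, "n_pairs") <- sum(keep)
  attr(counts, "attribution") <- attribution
  counts
}

#' Estimate stratified transition probability matrices
#'
#' Time-homogeneous maximum-likelihood estimate per severity stratum:
#' `P(i -> j | s) = n[i, j, s] / sum_j n[i, j, s]`. Rows with no outgoing
#' pairs yield `NA` entries (flagged); a stratum with no pairs at all is
#' omitted with a warning.
#'
#' @param counts A count array from [count_transitions()].
#' @return An object of class `markov_fit` with elements `P` (list of 2x2
#'   row-stochastic matrices by stratum), `counts`, `n_pairs`,
#'   `attribution` and `undefined_rows`.
#' @export
estimate_transitions <- function(counts) {
  strata <- dimnames(counts)$severity
  keep <- vapply(strata, function(s) sum(counts[, , s]) > 0, logical(1))
  if (!any(keep)) {
    abort("no transitions in any stratum", class = "airadmit_validation_error")
  }
  if (!all(keep)) {
    warn(paste0("stratum with no observed pairs omitted: ",
                paste(strata[!keep], collapse = ", ")))
  }
  strata <- strata[keep]
  undefined <- character(0)
  P <- lapply(strata, function(s) {
    m <- counts[, , s]
    rs <- rowSums(m)
    p <- matrix(NA_real_, 2, 2, dimnames = dimnames(counts)[1:2])
    for (i in 1:2) {
      if (rs[i] > 0) {
        # off-diagonal from the count ratio, diagonal as its exact
        # complement: rows sum to 1 in exact floating point
        p[i, 3 - i] <- m[i, 3 - i] / rs[i]
        p[i, i] <- 1 - p[i, 3 - i]
      }
    }
    if (any(rs == 0)) {
      undefined <<- c(undefined, paste0(s, ":from=", state_levels[rs == 0]))
    }
    p
  })
  names(P) <- strata
  structure(list(P = P, counts = counts[, , strata, drop = FALSE],
                 n_pairs = attr(counts, "n_pairs"),
                 attribution = attr(counts, "attribution"),
                 undefined_rows = undefined),
            class = "markov_fit")
}

#' Fit a severity-stratified two-state Markov chain
#'
#' Convenience composition of [count_transitions()] and
#' [estimate_transitions()], optionally followed by block-bootstrap
#' confidence intervals.
#'
#' @inheritParams count_transitions
#' @param boot_B Number of bootstrap replicates (0 skips the bootstrap).
#' @param boot_seed,boot_block_length Passed to [transition_bootstrap()].
#' @return A `markov_fit` object (with a `ci` element when `boot_B > 0`).
#' @export
fit_markov <- function(state, severity = NULL,
                       attribution = c("destination", "origin"),
                       boot_B = 0, boot_seed = NULL,
                       boot_block_length = NULL) {
  attribution <- match.arg(attribution)
  fit <- estimate_transitions(count_transitions(state, severity,
                                                attribution = attribution))
  if (boot_B > 0) {
    fit$ci <- transition_bootstrap(state, severity, B = boot_B,
                                   block_length = boot_block_length,
                                   seed = boot_seed,
                                   attribution = attribution)
  }
  fit
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("Stratified two-state Markov transition estimate (",
      x$n_pairs, " day pairs, ", x$attribution, "-day severity)\n", sep = "")
  for (s in names(x$P)) {
    cat("  stratum ", s, ":\n", sep = "")
    print(round(x$P[[s]], 4))
  }
  invisible(x)
}

#' @rdname fit_markov
#' @param x,object A `markov_fit` object.
#' @param ... Unused.
#' @export
tidy.markov_fit <- function(x, ...) {
  rows <- purrr::map_dfr(names(x$P), function(s) {
    p <- x$P[[s]]
    m <- x$counts[, , s]
    tidyr::crossing(from = 1:2, to = 1:2) %>%
      mutate(severity = s,
             estimate = purrr::map2_dbl(.data$from, .data$to,
                                        ~ p[.x, .y]),
             n = purrr::map2_int(.data$from, .data$to,
                                 ~ m[.x, .y])) %>%
      select("severity", "from", "to", "estimate", "n")
  })
  if (!is.null(x$ci)) {
    rows <- left_join(rows, x$ci$intervals,
                      by = c("severity", "from", "to"))
  }
  rows
}

#' @rdname fit_markov
#' @export
glance.markov_fit <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_strata = length(x$P),
         attribution = x$attribution,
         undefined_rows = length(x$undefined_rows))
}

#' @rdname fit_markov
#' @export
autoplot.markov_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$to),
                                   y = factor(.data$from, levels = c(2, 1)),
                                   fill = .data$estimate)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%%\n(n=%d)", 100 * .data$estimate, .data$n))) +
    ggplot2::facet_wrap(~severity) +
    ggplot2::scale_fill_gradient(low = "white", high = "indianred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "state at day t+1", y = "state at day t",
                  fill = "probability",
                  title = "Daily admission-state transition probabilities") +
    ggplot2::theme_minimal()
}

#' Stationary block-bootstrap intervals for transition probabilities
#'
#' Resamples days with the stationary bootstrap (blocks of consecutive days
#' with geometric length, mean `block_length`, circular wrap), re-estimates
#' the stratified transition matrices on each concatenated resample, and
#' returns per-entry 2.5/97.5 percentile intervals. Replicates in which a
#' stratum-row has no outgoing pairs contribute `NA` to that entry and are
#' counted as degenerate.
#'
#' @inheritParams count_transitions
#' @param B Number of replicates (>= 200 recommended).
#' @param block_length Mean block length in days; default `ceiling(n^(1/3))`.
#' @param seed Optional integer seed.
#' @return A list with `intervals` (tibble `severity`, `from`, `to`,
#'   `ci_low`, `ci_high`), `n_degenerate`, `B` and `block_length`.
#' @export
transition_bootstrap <- function(state, severity = NULL, B = 1000,
                                 block_length = NULL, seed = NULL,
                                 attribution = c("destination", "origin")) {
  attribution <- match.arg(attribution)
  n <- length(state)
  if (B < 2) abort("B must be >= 2", class = "airadmit_spec_error")
  if (is.null(block_length)) block_length <- max(2L, ceiling(n^(1 / 3)))
  point <- estimate_transitions(count_transitions(state, severity,
                                                  attribution = attribution))
  strata <- names(point$P)
  run <- function() {
    reps <- array(NA_real_, dim = c(2, 2, length(strata), B))
    degenerate <- 0L
    for (b in seq_len(B)) {
      idx <- stationary_boot_index(n, block_length)
      cnt <- tryCatch(
        count_transitions(state[idx],
                          if (is.null(severity)) NULL else severity[idx],
                          attribution = attribution),
        error = function(e) NULL)
      est <- if (is.null(cnt)) NULL else
        suppressWarnings(tryCatch(estimate_transitions(cnt),
                                  error = function(e) NULL))
      bad <- is.null(est) || !setequal(names(est$P), strata) ||
        any(vapply(est$P, anyNA, logical(1)))
      if (bad) degenerate <- degenerate + 1L
      if (!is.null(est)) {
        for (s in intersect(names(est$P), strata)) {
          reps[, , match(s, strata), b] <- est$P[[s]]
        }
      }
    }
    intervals <- purrr::map_dfr(seq_along(strata), function(si) {
      tidyr::crossing(from = 1:2, to = 1:2) %>%
        mutate(severity = strata[si],
               ci_low = purrr::map2_dbl(.data$from, .data$to, ~
                 quantile(reps[.x, .y, si, ], 0.025, na.rm = TRUE,
                          names = FALSE)),
               ci_high = purrr::map2_dbl(.data$from, .data$to, ~
                 quantile(reps[.x, .y, si, ], 0.975, na.rm = TRUE,
                          names = FALSE))) %>%
        select("severity", "from", "to", "ci_low", "ci_high")
    })
    list(intervals = intervals, n_degenerate = degenerate, B = B,
         block_length = block_length)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# One circular stationary-bootstrap index vector of length n.
stationary_boot_index <- function(n, mean_block) {
  p_new <- 1 / mean_block
  idx <- integer(n)
  pos <- sample.int(n, 1)
  for (t in seq_len(n)) {
    idx[t] <- pos
    if (runif(1) < p_new) {
      pos <- sample.int(n, 1)
    } else {
      pos <- if (pos == n) 1L else pos + 1L
    }
  }
  idx
}

#' Severe-minus-mild transition probability differences
#'
#' For a fit with both severity strata, returns the per-entry difference
#' `P(i -> j | severe) - P(i -> j | mild)` in percentage points.
#'
#' @param fit A `markov_fit` estimated with both `mild` and `severe` strata.
#' @return A tibble with `from`, `to`, `p_severe`, `p_mild`, `diff_pp`.
#' @export
compare_conditions <- function(fit) {
  if (!all(c("mild", "severe") %in% names(fit$P))) {
    abort("fit must contain both 'mild' and 'severe' strata",
          class = "airadmit_spec_error")
  }
  ps <- fit$P[["severe"]]
  pm <- fit$P[["mild"]]
  tidyr::crossing(from = 1:2, to = 1:2) %>%
    mutate(
      p_severe = purrr::map2_dbl(.data$from, .data$to, ~ ps[.x, .y]),
      p_mild = purrr::map2_dbl(.data$from, .data$to, ~ pm[.x, .y]),
      diff_pp = 100 * (.data$p_severe - .data$p_mild)
    )
}
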