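test_that("transition counts tally consecutive day pairs", {
  cnt <- count_transitions(c(1, 2, 2, 1, 2), severity = rep(1, 5))
  expect_equal(unname(cnt["1", "1", "severe"]), 0L)
  expect_equal(unname(cnt["1", "2", "severe"]), 2L)
  expect_equal(unname(cnt["2", "1", "severe"]), 1L)
  expect_equal(unname(cnt["2", "2", "severe"]), 1L)
  expect_equal(attr(cnt, "n_pairs"), 4L)

  cnt2 <- count_transitions(c(1, 1, 1))
  expect_equal(unname(cnt2["1", "1", "all"]), 2L)
  expect_equal(sum(cnt2), 2L)
})

test_that("severity flips partition the pairs exactly across strata", {
  withr::local_seed(40)
  state <- sample(1:2, 200, replace = TRUE)
  severity <- c(rep(0, 100), rep(1, 100))
  cnt <- count_transitions(state, severity)
  expect_equal(sum(cnt), 199L)
  expect_equal(sum(cnt[, , "mild"]) + sum(cnt[, , "severe"]), 199L)
  # destination-day convention: pair 100 -> 101 goes to the severe stratum
  expect_equal(sum(cnt[, , "severe"]), 100L)
  # origin-day convention shifts that boundary pair to mild
  cnt_o <- count_transitions(state, severity, attribution = "origin")
  expect_equal(sum(cnt_o[, , "severe"]), 99L)
})

test_that("undefined states and severities break pairs cleanly", {
  cnt <- count_transitions(c(1, 2, NA, 2, 2), severity = rep(1, 5))
  expect_equal(attr(cnt, "n_pairs"), 2L)  # (1,2) and (2,2)
  expect_error(count_transitions(c(1, NA, 1), severity = c(1, NA, NA)),
               class = "airadmit_validation_error")
})

test_that("stratified MLE normalises rows and flags empty ones", {
  cnt <- count_transitions(c(1, 2, 2, 1, 2), severity = rep(1, 5))
  fit <- suppressWarnings(estimate_transitions(cnt))
  P <- fit$P[["severe"]]
  expect_equal(unname(P["1", "2"]), 1)        # forced row: n11 = 0, n12 = 2
  expect_equal(unname(P["2", "1"]), 0.5)
  expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)

  # a chain that never leaves state 1 leaves row 2 undefined
  fit1 <- suppressWarnings(fit_markov(rep(1, 10), severity = rep(1, 10)))
  expect_true(all(is.na(fit1$P[["severe"]]["2", ])))
  expect_match(fit1$undefined_rows, "severe", all = TRUE)
  # the empty mild stratum is omitted with a warning
  expect_warning(estimate_transitions(
    count_transitions(rep(1, 10), severity = rep(1, 10))), "omitted")
})

test_that("single-stratum estimate equals a brute-force pair scan", {
  withr::local_seed(41)
  state <- sample(1:2, 500, replace = TRUE, prob = c(0.6, 0.4))
  fit <- fit_markov(state)
  brute <- matrix(0, 2, 2)
  for (t in seq_len(499)) {
    brute[state[t], state[t + 1]] <- brute[state[t], state[t + 1]] + 1
  }
  brute <- brute / rowSums(brute)
  expect_equal(unname(fit$P[["all"]]), brute, tolerance = 1e-12)
})

test_that("swapping the severity labels swaps the estimated matrices", {
  ch <- simulate_state_chain(2000, REF_SEVERE_ALL, REF_MILD_ALL, seed = 42)
  sev <- as.integer(ch$severity == "severe")
  f1 <- fit_markov(ch$state, sev)
  f2 <- fit_markov(ch$state, 1L - sev)
  expect_equal(f1$P[["severe"]], f2$P[["mild"]])
  expect_equal(f1$P[["mild"]], f2$P[["severe"]])
})

test_that("stratified MLE recovers both generating matrices at n = 2e5", {
  ch <- simulate_state_chain(200000, REF_SEVERE_ALL, REF_MILD_ALL,
                             p_severe = 0.3, seed = 43)
  fit <- fit_markov(ch$state, ch$severity)
  for (i in 1:2) for (j in 1:2) {
    expect_lt(abs(fit$P[["severe"]][i, j] - REF_SEVERE_ALL[i, j]), 0.005)
    expect_lt(abs(fit$P[["mild"]][i, j] - REF_MILD_ALL[i, j]), 0.005)
  }
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_equal(sum(td$n), fit$n_pairs)
  g <- glance(fit)
  expect_equal(g$n_strata, 2L)
})

test_that("bootstrap gives degenerate-width intervals for a frozen chain", {
  fit <- suppressWarnings(
    fit_markov(rep(1L, 60), severity = rep(1L, 60), boot_B = 50,
               boot_seed = 44))
  ci <- fit$ci$intervals
  row11 <- ci[ci$from == 1 & ci$to == 1 & ci$severity == "severe", ]
  expect_equal(row11$ci_low, 1)
  expect_equal(row11$ci_high, 1)
})

test_that("bootstrap intervals are seed-reproducible and cover the truth", {
  ch <- simulate_state_chain(3000, REF_SEVERE_ALL, REF_MILD_ALL,
                             p_severe = 0.4, seed = 45)
  b1 <- transition_bootstrap(ch$state, ch$severity, B = 200, seed = 46)
  b2 <- transition_bootstrap(ch$state, ch$severity, B = 200, seed = 46)
  expect_identical(b1$intervals, b2$intervals)
  ci12 <- b1$intervals[b1$intervals$severity == "severe" &
                         b1$intervals$from == 1 & b1$intervals$to == 2, ]
  expect_true(ci12$ci_low <= REF_SEVERE_ALL[1, 2] &
                REF_SEVERE_ALL[1, 2] <= ci12$ci_high)
  expect_lt(ci12$ci_low, ci12$ci_high)
})

test_that("condition comparison reproduces differences of known matrices", {
  # counts proportional to the matrices give back the matrices exactly
  make_counts <- function(mild, severe) {
    cnt <- array(0L, dim = c(2, 2, 2),
                 dimnames = list(from = c("1", "2"), to = c("1", "2"),
                                 severity = c("mild", "severe")))
    cnt[, , "mild"] <- round(mild * 10000)
    cnt[, , "severe"] <- round(severe * 10000)
    attr(cnt, "n_pairs") <- sum(cnt)
    cnt
  }
  fit <- estimate_transitions(make_counts(REF_MILD_ALL, REF_SEVERE_ALL))
  cmp <- compare_conditions(fit)
  expect_equal(cmp$diff_pp[cmp$from == 1 & cmp$to == 2], 15.38,
               tolerance = 1e-10)
  fit_fc <- estimate_transitions(make_counts(REF_MILD_FC, REF_SEVERE_FC))
  cmp_fc <- compare_conditions(fit_fc)
  expect_equal(cmp_fc$diff_pp[cmp_fc$from == 1 & cmp_fc$to == 2], 30.05,
               tolerance = 1e-10)

  # identical strata difference is exactly zero
  fit0 <- estimate_transitions(make_counts(REF_MILD_ALL, REF_MILD_ALL))
  expect_equal(compare_conditions(fit0)$diff_pp, rep(0, 4))
  plt <- autoplot(fit)
  expect_s3_class(plt, "ggplot")
})
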