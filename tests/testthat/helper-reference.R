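# Ground-truth values used across the parameter-recovery tests: the study
# setting's reported transition matrices (full sample and female-cold
# subgroup, by pollution severity), headline SO2 effect and selected-index
# odds ratio. In the tests these serve as *generator inputs* that the
# estimators must recover.

ref_tpm <- function(p11, p12, p21, p22) {
  matrix(c(p11, p12, p21, p22), nrow = 2, byrow = TRUE,
         dimnames = list(from = c("1", "2"), to = c("1", "2")))
}

REF_SEVERE_ALL <- ref_tpm(0.6454, 0.3546, 0.3366, 0.6634)
REF_MILD_ALL <- ref_tpm(0.7992, 0.2008, 0.3557, 0.6443)
REF_SEVERE_FC <- ref_tpm(0.6994, 0.3006, 0.3114, 0.6886)
REF_MILD_FC <- ref_tpm(0.9999, 0.0001, 0.3938, 0.6062)

REF_SO2_PCT_LAG01 <- 7.27   # percent increase per 10 ug/m3, lag0-1
REF_SELECTED_OR <- 4.02     # selected severity index odds ratio

# Simulate a single-regime chain of length n governed by matrix P, with the
# severity label fixed to "severe" or "mild".
ref_chain <- function(n, P, label = c("severe", "mild"), seed = NULL) {
  label <- match.arg(label)
  simulate_state_chain(
    n, p_severe_matrix = P, p_mild_matrix = P,
    severity = rep(if (label == "severe") 1L else 0L, n), seed = seed
  )
}

# Merge two chains so transition pairs never span the join.
chain_concat <- function(...) {
  chains <- list(...)
  state <- integer(0)
  severity <- character(0)
  for (ch in chains) {
    state <- c(state, NA_integer_, ch$state)
    severity <- c(severity, NA_character_, as.character(ch$severity))
  }
  list(state = state[-1], severity = severity[-1])
}
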