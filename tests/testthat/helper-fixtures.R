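# Shared fixtures and independent oracles. The synthetic study cohort mirrors
# the calibration study's conditions: n = 1408 complete respondents with a
# standard-normal latent trait, responses drawn from the bundled bank. It is
# computed once per test run and shared across files.

.fixtures <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(aaq_bank(), n = 1408, seed = 1)
  .fixtures$cohort
}

# post-hoc CAT runs of the three studied stopping rules over the shared cohort
study_runs <- function() {
  if (is.null(.fixtures$runs)) {
    bank <- aaq_bank()
    co <- study_cohort()
    .fixtures$runs <- lapply(c(cap17 = 17, cap10 = 10, cap5 = 5), function(cap)
      run_cohort(bank, co$responses, rule = stopping_rule(0.3, cap)))
  }
  .fixtures$runs
}

# full-pattern (non-adaptive) EAP scoring of the shared cohort
study_full_scores <- function() {
  if (is.null(.fixtures$full))
    .fixtures$full <- score_respondents(aaq_bank(), study_cohort()$responses)
  .fixtures$full
}

# Fisher information oracle: -E[d2/dtheta2 log P] by central finite differences
# of the category log-probabilities, independent of the analytic derivative
fd_item_information <- function(item, theta, h = 1e-4) {
  vapply(theta, function(t0) {
    P0 <- grm_cat_prob(item, t0)[, 1]
    Pp <- grm_cat_prob(item, t0 + h)[, 1]
    Pm <- grm_cat_prob(item, t0 - h)[, 1]
    d2 <- (log(Pp) - 2 * log(P0) + log(Pm)) / h^2
    -sum(P0 * d2)
  }, 0)
}

# maximum-covariance oracle: the comonotone coupling of two empirical margins
# is sorting both samples and pairing them off
sorted_cov_max <- function(x, y) {
  mean(sort(x) * sort(y)) - mean(x) * mean(y)
}

# brute-force summed-score distribution: enumerate every response pattern
enum_score_dist <- function(bank, theta) {
  m <- n_categories(bank)
  pats <- as.matrix(expand.grid(lapply(m, seq_len)))
  probs <- lapply(seq_along(bank$items), function(i)
    grm_cat_prob(bank$items[[i]], theta)[, 1])
  out <- numeric(sum(m - 1L) + 1L)
  for (r in seq_len(nrow(pats))) {
    p <- prod(vapply(seq_along(m), function(i) probs[[i]][pats[r, i]], 0))
    s <- sum(pats[r, ] - 1L)
    out[s + 1L] <- out[s + 1L] + p
  }
  out
}
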