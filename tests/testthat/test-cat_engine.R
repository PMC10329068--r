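bank <- aaq_bank()

test_that("stopping rule validates its fields", {
  r <- stopping_rule(0.3, max_items = 10)
  expect_identical(r$min_items, 1L)
  expect_error(stopping_rule(0, max_items = 5))
  expect_error(stopping_rule(0.3, max_items = 5, min_items = 6))
})

test_that("MFI selection takes the information argmax, ties to bank order", {
  one <- item_bank(bank$items[1])
  expect_identical(select_next_item(one, integer(0), 0), 1L)

  twin <- item_bank(list(graded_item("a", 2, c(-1, 1)), graded_item("b", 2, c(-1, 1))))
  expect_identical(select_next_item(twin, integer(0), 0.3), 1L)
  expect_identical(select_next_item(twin, 1L, 0.3), 2L)
  expect_error(select_next_item(twin, 1:2, 0), "all items administered")

  # manual argmax at a few trait values
  for (th in c(-1, 0, 1.5)) {
    info <- vapply(bank$items, item_information, 0, theta = th)
    expect_identical(select_next_item(bank, integer(0), th),
                     which.max(info))
  }
  # the first item picked at the prior mean is one of the high-exposure items
  expect_true(select_next_item(bank, integer(0), 0) %in% c(4, 6, 7, 12, 13, 14))
})

test_that("run_cat respects the stopping rule and records a consistent session", {
  set.seed(12)
  pat <- simulate_responses(bank, 0.4)[1, ]
  rec5 <- run_cat(bank, pattern_provider(pat), stopping_rule(0.3, max_items = 5))
  expect_lte(length(rec5$item_ids), 5L)
  expect_identical(anyDuplicated(rec5$item_ids), 0L)
  expect_identical(nrow(rec5$trajectory), length(rec5$item_ids))

  rec <- run_cat(bank, pattern_provider(pat), stopping_rule(0.3, max_items = 17))
  if (rec$stop_reason == "se_met") expect_lte(rec$final$se, 0.3)
  expect_error(run_cat(bank, pattern_provider(pat), stopping_rule(0.3, 18)),
               "exceeds bank size")
  expect_error(pattern_provider(c(1L, NA)), "complete pattern")
})

test_that("the all-lowest pattern runs the full bank and scores like the full pattern", {
  rec <- run_cat(bank, pattern_provider(rep(1L, 17)), stopping_rule(0.3, 17))
  expect_identical(rec$stop_reason, "max_items")
  expect_length(rec$item_ids, 17L)
  expect_gt(rec$final$se, 0.3)
  # the bank carries too little information at the low-limitation extreme
  expect_lt(test_information(bank, rec$final$theta), 1 / 0.3^2 - 1)
  full <- score_respondents(bank, matrix(rep(1L, 17), 1))
  expect_equal(rec$score_0_100, full$irt_0_100)
  expect_equal(rec$final$theta, full$theta)
})

test_that("post-hoc cohort runs are deterministic and match single sessions", {
  co <- study_cohort()
  sub <- co$responses[1:40, ]
  rule <- stopping_rule(0.3, 10)
  r1 <- run_cohort(bank, sub, rule = rule)
  r2 <- run_cohort(bank, sub, rule = rule)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$sequences, r2$sequences)

  for (r in c(1, 17, 33)) {
    rec <- run_cat(bank, pattern_provider(sub[r, ]), rule)
    expect_identical(r1$sequences[[r]], rec$item_index)
    expect_equal(r1$records$theta[r], rec$final$theta)
    expect_identical(r1$records$stop_reason[r], rec$stop_reason)
  }
})

test_that("simulee mode is seed-reproducible and equals its post-hoc replay", {
  th <- c(-0.5, 0.2, 1.1)
  r1 <- run_cohort(bank, thetas = th, rule = stopping_rule(0.3, 17), seed = 6)
  r2 <- run_cohort(bank, thetas = th, rule = stopping_rule(0.3, 17), seed = 6)
  expect_identical(r1$records, r2$records)

  p1 <- simulee_provider(bank, 0.7, seed = 11)
  p2 <- simulee_provider(bank, 0.7, seed = 11)
  expect_identical(vapply(1:17, p1, 0L), vapply(1:17, p2, 0L))
  expect_identical(p1(3), p1(3))   # repeated queries agree
})

test_that("incomplete rows are skipped in post-hoc mode", {
  x <- study_cohort()$responses[1:5, ]
  x[2, 4] <- NA
  expect_warning(run <- run_cohort(bank, x, rule = stopping_rule(0.3, 5)),
                 "incomplete")
  expect_identical(nrow(run$records), 4L)
})

test_that("cohort-level invariants hold on the study runs", {
  runs <- study_runs()
  full_theta <- study_full_scores()$theta

  for (run in runs) {
    r <- run$records
    expect_true(all(r$se[r$stop_reason == "se_met"] <= 0.3))
    expect_true(all(r$n_items <= run$rule$max_items))
    # exposure rates sum to the mean test length
    expect_equal(sum(exposure_rates(run, bank)), mean(r$n_items))
  }

  # where the bank information covers se <= 0.3, the unrestricted CAT stops on
  # the se rule (a handful of boundary respondents sit at the threshold)
  high_info <- test_information(bank, full_theta) >= 1 / 0.3^2 - 1
  expect_gte(mean(runs$cap17$records$stop_reason[high_info] == "se_met"), 0.99)

  # final CAT estimates track the full-pattern estimates for all three rules
  for (run in runs)
    expect_gte(cor(run$records$theta, full_theta), 0.95)
})
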