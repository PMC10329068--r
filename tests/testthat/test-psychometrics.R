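bank <- aaq_bank()

test_that("Loevinger coefficients: Guttman scales give H = 1, noise gives H = 0", {
  # deterministic Guttman data: items are step functions of a common rank
  rank <- rep(1:20, 3)
  gutt <- cbind(pmin(5, pmax(1, rank - 2)),
                pmin(4, pmax(1, rank - 8)),
                pmin(5, pmax(1, rank - 12)))
  mk <- mokken_analysis(gutt, minsize = 5)
  expect_equal(mk$H, 1)
  expect_equal(unname(mk$Hi), rep(1, 3))
  expect_identical(sum(mk$violations), 0L)

  set.seed(4)
  indep <- matrix(sample(1:5, 5000 * 6, replace = TRUE), 5000, 6)
  expect_lt(abs(mokken_analysis(indep)$H), 0.05)
})

test_that("pairwise H_ij equals the sorted-margin covariance-ratio oracle", {
  set.seed(77)
  for (r in 1:5) {
    x <- cbind(sample(1:4, 6, replace = TRUE), sample(1:3, 6, replace = TRUE))
    while (any(apply(x, 2, var) == 0))
      x <- cbind(sample(1:4, 6, replace = TRUE), sample(1:3, 6, replace = TRUE))
    mk <- mokken_analysis(x, minsize = 2)
    n <- nrow(x)
    oracle <- (cov(x[, 1], x[, 2]) * (n - 1) / n) / sorted_cov_max(x[, 1], x[, 2])
    expect_equal(mk$Hij[1, 2], oracle, tolerance = 1e-12)
  }
  expect_error(mokken_analysis(cbind(rep(1, 10), sample(1:3, 10, TRUE))),
               "zero-variance")
})

test_that("residual correlations are symmetric and flag induced dependence", {
  set.seed(9)
  th <- rnorm(800)
  x <- simulate_responses(bank, th)
  rc <- residual_correlations(x, bank)
  expect_true(isSymmetric(rc$correlations))
  expect_true(all(is.na(diag(rc$correlations))))
  expect_gte(rc$prop_below, 0.95)   # unidimensional data: pairs stay below 0.20

  # an exact duplicate of item 1 is maximally locally dependent with it
  aug <- item_bank(c(bank$items, list(
    graded_item("AAQ_dup", a = bank$items[[1]]$a, b = bank$items[[1]]$b))))
  rc2 <- residual_correlations(cbind(x, AAQ_dup = x[, 1]), aug)
  expect_true(any(rc2$flagged$item1 == "AAQ_01" & rc2$flagged$item2 == "AAQ_dup"))
  expect_gt(rc2$correlations["AAQ_01", "AAQ_dup"], 0.9)
})

test_that("Lord-Wingersky recursion reproduces closed forms and enumeration", {
  # two binary items at fixed theta: (q1q2, p1q2 + q1p2, p1p2)
  two <- item_bank(list(graded_item("x", a = 1.2, b = 0.3),
                        graded_item("y", a = 0.8, b = -0.5)))
  th <- 0.7
  p <- vapply(two$items, function(it) grm_cum_prob(it, th)[1, 1], 0)
  expect_equal(unname(summed_score_distribution(two, th)[, 1]),
               c((1 - p[1]) * (1 - p[2]),
                 p[1] * (1 - p[2]) + (1 - p[1]) * p[2],
                 p[1] * p[2]), tolerance = 1e-14)

  # three polytomous items: recursion equals exhaustive pattern enumeration
  toy <- item_bank(bank$items[c(2, 9, 16)])
  for (th in c(-1.2, 0, 1.4))
    expect_equal(unname(summed_score_distribution(toy, th)[, 1]),
                 enum_score_dist(toy, th), tolerance = 1e-10)

  # probability conservation at every quadrature node
  g <- quadrature_grid()
  f <- summed_score_distribution(bank, g$nodes)
  expect_equal(colSums(f), rep(1, length(g$nodes)), tolerance = 1e-12)
})

test_that("S-X2 keeps its size on model-consistent calibrated data", {
  rejections <- logical(0)
  crit_fail <- integer(0)
  for (r in 1:8) {
    set.seed(100 + r)
    x <- simulate_responses(bank, rnorm(1408))
    fit <- grm(x, control = grm_control(tol = 5e-4, max_cycles = 200))
    sf <- sx2_item_fit(x, fit$bank)
    expect_true(all(sf$statistic >= 0))
    expect_true(all(sf$df >= 1L))
    rejections <- c(rejections, sf$p_value < 0.05)
    crit_fail <- c(crit_fail, sum(sf$flagged))
  }
  expect_lte(mean(rejections), 0.10)   # no type-I inflation
  # the 0.003 misfit criterion passes for every item in nearly all replicates
  expect_gte(mean(crit_fail == 0L), 7 / 8)
})

test_that("DIF scan is label-symmetric, null under no DIF, powered under DIF", {
  set.seed(21)
  g <- rep(c("A", "B"), each = 700)
  xA <- simulate_responses(bank, rnorm(700))
  shifted <- bank
  shifted$items[[6]]$b <- shifted$items[[6]]$b + 1.0   # uniform DIF, item 6
  xB <- simulate_responses(shifted, rnorm(700))
  x <- rbind(xA, xB)

  dif <- dif_scan(x, g, bank)
  expect_true(all(dif$r2_change >= 0))
  expect_gte(dif$r2_change[6], 0.02)            # injected DIF is flagged
  expect_true(all(dif$r2_change[-6] < 0.02))    # the clean items are not

  swapped <- dif_scan(x, ifelse(g == "A", "B", "A"), bank)
  expect_equal(dif$r2_change, swapped$r2_change, tolerance = 1e-4)

  expect_error(dif_scan(x, rep("A", 1400), bank), "binary")
  expect_error(dif_scan(x[1:3, ], c("A", "A", "B"), bank), "at least 2")
})

test_that("modal-category scan flags tightly spaced thresholds", {
  wide <- graded_item("w", a = 2, b = c(-2, 0, 2))
  expect_length(modal_category_check(item_bank(list(wide)))$never_modal$w, 0L)

  tight <- graded_item("t", a = 2, b = c(0, 0.1, 2))
  mc <- modal_category_check(item_bank(list(tight)))
  expect_identical(mc$never_modal$t, 2L)

  aaq <- modal_category_check(bank)
  expect_length(aaq$flagged_items, 4L)
})
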