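bank <- aaq_bank()

test_that("quadrature grid is normalized and ordered", {
  g <- quadrature_grid()
  expect_true(all(diff(g$nodes) > 0))
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_true(all(g$weights > 0))
})

test_that("EAP with no responses recovers the prior", {
  est <- eap_estimate(bank, rep(NA_integer_, 17))
  expect_equal(est$theta, 0, tolerance = 1e-10)
  expect_equal(est$se, 1, tolerance = 0.01)   # grid truncation only
  expect_identical(est$n_items, 0L)
})

test_that("EAP matches a ten-times-finer integration oracle", {
  fine <- quadrature_grid(n = 601)
  set.seed(31)
  for (r in 1:20) {
    x <- simulate_responses(bank, rnorm(1))[1, ]
    x[sample(17, 5)] <- NA            # partial patterns too
    e <- eap_estimate(bank, x)
    o <- eap_estimate(bank, x, fine)
    expect_equal(e$theta, o$theta, tolerance = 1e-3)
    expect_equal(e$se, o$se, tolerance = 1e-3)
  }
})

test_that("EAP shrinks within the grid and rejects bad categories", {
  lo <- eap_estimate(bank, rep(1L, 17))
  hi <- eap_estimate(bank, n_categories(bank))
  expect_gt(lo$theta, -6)
  expect_lt(hi$theta, 6)
  expect_error(eap_estimate(bank, c(7L, rep(1L, 16))), "categories are 1..")
})

test_that("posterior se decreases, in expectation, as items are added", {
  set.seed(8)
  th <- rnorm(150)
  x <- simulate_responses(bank, th)
  mean_se <- vapply(1:17, function(k) {
    part <- x
    if (k < 17) part[, (k + 1):17] <- NA
    mean(score_respondents(bank, part)$se)
  }, 0)
  expect_true(all(diff(mean_se) < 0))
})

test_that("score_respondents reports both metrics with correct orientation", {
  pats <- rbind(lowest = rep(1L, 17), highest = n_categories(bank))
  sc <- score_respondents(bank, pats)
  expect_equal(sc$original_0_100, c(100, 0))
  expect_equal(sc$irt_0_100[1], 98.6, tolerance = 0.05)
  expect_equal(sc$irt_0_100[2], 2.3, tolerance = 0.05)

  # partial pattern: model score only; empty pattern: flagged, no scores
  part <- matrix(c(2L, rep(NA_integer_, 16)), 1)
  expect_true(is.na(score_respondents(bank, part)$original_0_100))
  expect_false(is.na(score_respondents(bank, part)$irt_0_100))
  expect_warning(none <- score_respondents(bank, matrix(NA_integer_, 1, 17)),
                 "unscored")
  expect_true(all(is.na(none[, c("theta", "se", "irt_0_100")])))

  # on the study-sized cohort the two metrics nearly coincide
  full <- study_full_scores()
  expect_gte(cor(full$original_0_100, full$irt_0_100), 0.99)
})

test_that("EM calibration matches a direct marginal-ML oracle on binary toys", {
  toy <- item_bank(list(graded_item("t1", a = 1.6, b = 0.4),
                        graded_item("t2", a = 1.0, b = -0.6),
                        graded_item("t3", a = 2.2, b = 0.9)))
  x <- simulate_responses(toy, rnorm(2000), seed = 5)
  fit <- grm(x, control = grm_control(tol = 1e-6, max_cycles = 2000))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) > -1e-8))

  # independent path: direct joint-likelihood maximization over the 8 possible
  # patterns with adaptive quadrature over the latent trait
  pats <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  counts <- table(factor(paste(x[, 1], x[, 2], x[, 3]),
                         levels = paste(pats[, 1], pats[, 2], pats[, 3])))
  negll <- function(p) {
    a <- exp(p[1:3]); b <- p[4:6]
    lp <- vapply(seq_len(8), function(r) {
      f <- function(th) {
        pr <- dnorm(th)
        for (i in 1:3) {
          ps <- plogis(a[i] * (th - b[i]))
          pr <- pr * (if (pats[r, i] == 2) ps else 1 - ps)
        }
        pr
      }
      log(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
    }, 0)
    -sum(as.numeric(counts) * lp)
  }
  o <- optim(rep(0, 6), negll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))
  est <- coef(fit)
  expect_equal(unname(est[, "a"]), exp(o$par[1:3]), tolerance = 1e-3)
  expect_equal(unname(est[, "b1"]), o$par[4:6], tolerance = 1e-3)
})

test_that("calibration guards its preconditions", {
  x <- simulate_responses(bank, rnorm(60), seed = 2)
  x[x[, 3] == 6L, 3] <- 5L                           # wipe out a category
  expect_error(suppressWarnings(grm(x, n_categories = n_categories(bank))),
               "collapse categories")
  y <- simulate_responses(item_bank(bank$items[1:4]), rnorm(30), seed = 4)
  expect_warning(try(grm(y, control = grm_control(max_cycles = 1)), silent = TRUE),
                 "unstable")
})
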