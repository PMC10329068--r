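#' Mokken scale analysis: Loevinger scalability and monotonicity
#'
#' Computes polytomous Loevinger coefficients `H_ij = cov(X_i, X_j) /
#' cov_max(X_i, X_j)`, where `cov_max` is the covariance of the comonotonic
#' coupling of the two observed margins (the maximum attainable with those
#' margins), aggregated to item coefficients `H_i` and the scale coefficient
#' `H`. Monotonicity is checked with rest-score groups: respondents are
#' grouped on their rest score (total minus the item), adjacent rest scores
#' are merged until every group holds at least `minsize` respondents, and
#' decreases (beyond `minvi`) of the item-step proportions `P(X_i >= k)`
#' across increasing rest-score groups are counted as violations.
#'
#' Rows with any missing response are dropped (listwise) with a message.
#'
#' @param responses Integer matrix, respondents x items, categories `1..m_i`.
#' @param minsize Minimum rest-score group size; default `n/10` capped at 50.
#' @param minvi Smallest decrease counted as a violation (default 0.03).
#' @return An object of class `mokken_result`: scale `H`, per-item `Hi`,
#'   pairwise `Hij` (symmetric matrix), and `violations` per item.
#' @export
mokken_analysis <- function(responses, minsize = NULL, minvi = 0.03) {
  x <- as.matrix(responses)
  J <- ncol(x)
  if (J < 2L) stop("need at least 2 items", call. = FALSE)
  cc <- rowSums(is.na(x)) == 0L
  if (!all(cc)) {
    message(sum(!cc), " incomplete row(s) dropped (listwise)")
    x <- x[cc, , drop = FALSE]
  }
  n <- nrow(x)
  if (is.null(minsize)) minsize <- min(50L, max(1L, floor(n / 10)))
  if (any(apply(x, 2, stats::var) == 0))
    stop("zero-variance item", call. = FALSE)

  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("item_%02d", seq_len(J))
  cov_obs <- matrix(NA_real_, J, J, dimnames = list(ids, ids))
  cov_max <- cov_obs
  for (i in seq_len(J - 1L)) for (j in (i + 1L):J) {
    cov_obs[i, j] <- cov_obs[j, i] <- stats::cov(x[, i], x[, j]) * (n - 1) / n
    cov_max[i, j] <- cov_max[j, i] <- comonotone_cov(x[, i], x[, j])
  }
  Hij <- cov_obs / cov_max
  off <- upper.tri(Hij)
  H <- sum(cov_obs[off]) / sum(cov_max[off])
  Hi <- vapply(seq_len(J), function(i)
    sum(cov_obs[i, -i]) / sum(cov_max[i, -i]), 0)
  viol <- vapply(seq_len(J), function(i)
    monotonicity_violations(x[, i], rowSums(x[, -i, drop = FALSE]),
                            minsize, minvi), 0L)
  structure(list(H = H, Hi = stats::setNames(Hi, ids), Hij = Hij,
                 violations = stats::setNames(viol, ids),
                 n = n, minsize = minsize, minvi = minvi),
            class = "mokken_result")
}

# maximum covariance attainable given the two observed margins: covariance of
# the comonotonic joint P(X = a, Y = b) built by quantile coupling
comonotone_cov <- function(x, y) {
  vx <- sort(unique(x)); vy <- sort(unique(y))
  Fx <- cumsum(tabulate(match(x, vx))) / length(x)
  Fy <- cumsum(tabulate(match(y, vy))) / length(y)
  exy <- 0
  for (a in seq_along(vx)) for (b in seq_along(vy)) {
    p <- max(0, min(Fx[a], Fy[b]) -
                  max(if (a > 1) Fx[a - 1] else 0, if (b > 1) Fy[b - 1] else 0))
    exy <- exy + p * vx[a] * vy[b]
  }
  exy - mean(x) * mean(y)
}

monotonicity_violations <- function(item, rest, minsize, minvi) {
  ord <- order(rest)
  item <- item[ord]; rest <- rest[ord]
  # merge adjacent rest-score values until every group reaches minsize
  groups <- integer(length(rest))
  g <- 1L; count <- 0L; last_val <- rest[1]
  for (r in seq_along(rest)) {
    if (rest[r] != last_val && count >= minsize) { g <- g + 1L; count <- 0L }
    groups[r] <- g; count <- count + 1L; last_val <- rest[r]
  }
  if (count < minsize && g > 1L) groups[groups == g] <- g - 1L
  ng <- max(groups)
  if (ng < 2L) return(0L)
  viol <- 0L
  for (k in 2:max(item)) {
    prop <- vapply(seq_len(ng), function(gr)
      mean(item[groups == gr] >= k), 0)
    viol <- viol + sum(diff(prop) < -minvi)
  }
  viol
}

#' @export
print.mokken_result <- function(x, ...) {
  cat(sprintf("Mokken scale analysis (n = %d)\n", x$n))
  cat(sprintf("  scale H = %.3f\n", x$H))
  cat(sprintf("  item H_i: %.3f - %.3f; monotonicity violations: %d\n",
              min(x$Hi), max(x$Hi), sum(x$violations)))
  invisible(x)
}

#' Local independence screening via residual correlations
#'
#' Q3-style diagnostic: per respondent and item the residual is the observed
#' category minus the model-expected category at the respondent's full-pattern
#' EAP estimate, `e_ri = x_ri - E[X_i | theta_r]`. Pairwise Pearson
#' correlations of these residuals should be near zero under local
#' independence; pairs with `|r|` above the flag threshold (0.20) indicate
#' locally dependent items.
#'
#' @param responses Complete integer response matrix.
#' @param bank The calibrated `item_bank` for these items.
#' @param grid A [quadrature_grid()].
#' @param flag_threshold Absolute correlation above which a pair is flagged.
#' @return An object of class `local_dependence_result`: `correlations`
#'   (symmetric matrix, `NA` diagonal), `flagged` (data frame of flagged
#'   pairs) and `prop_below` (share of pairs at or below the threshold).
#' @export
residual_correlations <- function(responses, bank, grid = quadrature_grid(),
                                  flag_threshold = 0.20) {
  resp <- check_responses(responses, bank)
  if (any(apply(resp, 2, function(v) length(unique(v[!is.na(v)]))) < 2L))
    stop("item with fewer than 2 observed categories", call. = FALSE)
  post <- eap_from_loglik(loglik_matrix(resp, node_logprobs(bank, grid)), grid)
  expected <- vapply(bank$items, function(it) {
    P <- grm_cat_prob(it, post$theta)
    colSums(P * seq_len(nrow(P)))
  }, numeric(nrow(resp)))
  res <- resp - expected
  r <- stats::cor(res)
  diag(r) <- NA_real_
  off <- upper.tri(r)
  flagged <- which(abs(r) > flag_threshold & off, arr.ind = TRUE)
  ids <- item_ids(bank)
  structure(list(
    correlations = r,
    flagged = data.frame(item1 = ids[flagged[, 1]], item2 = ids[flagged[, 2]],
                         r = r[flagged]),
    prop_below = mean(abs(r[off]) <= flag_threshold),
    flag_threshold = flag_threshold),
    class = "local_dependence_result")
}

#' @export
print.local_dependence_result <- function(x, ...) {
  cat(sprintf("Residual correlations: |r| <= %.2f in %.1f%% of item pairs\n",
              x$flag_threshold, 100 * x$prop_below))
  if (nrow(x$flagged)) print(x$flagged)
  invisible(x)
}

#' Summed-score distribution by the generalized Lord-Wingersky recursion
#'
#' Probability of each raw summed score (0-based: category code minus one,
#' summed over items) at given theta values, computed by convolving the items'
#' category distributions one item at a time.
#'
#' @param bank An `item_bank`.
#' @param theta Numeric vector of latent values.
#' @param items Optional subset of item indices (default: all).
#' @return Matrix of probabilities, `(max score + 1)` rows (scores `0..S`) by
#'   `length(theta)` columns; columns sum to 1.
#' @export
summed_score_distribution <- function(bank, theta, items = NULL) {
  if (is.null(items)) items <- seq_len(length(bank))
  f <- matrix(1, 1, length(theta))
  for (i in items) {
    P <- grm_cat_prob(bank$items[[i]], theta)   # m x T
    m <- nrow(P)
    g <- matrix(0, nrow(f) + m - 1L, length(theta))
    for (k in seq_len(m))
      g[(k - 1L) + seq_len(nrow(f)), ] <- g[(k - 1L) + seq_len(nrow(f)), ] +
        f * rep(P[k, ], each = nrow(f))
    f <- g
  }
  rownames(f) <- 0:(nrow(f) - 1L)
  f
}

#' Orlando-Thissen S-X2 item fit
#'
#' Compares each item's observed category frequencies, conditional on the raw
#' summed score, with the model-predicted conditional frequencies. The
#' prediction integrates, over the quadrature prior, the item's category
#' probabilities times the Lord-Wingersky summed-score distribution of the
#' remaining items. Adjacent summed-score groups are merged until every
#' expected cell is at least `min_expected` and at least 80% of cells reach 5;
#' within merged groups sparse categories are pooled with their neighbor. The
#' Pearson statistic over the remaining cells is referred to a chi-square with
#' `df = (cells - groups) - n item parameters` (floored at 1).
#'
#' @param responses Complete integer response matrix.
#' @param bank Calibrated `item_bank`.
#' @param grid A [quadrature_grid()].
#' @param min_expected Smallest allowed expected cell count.
#' @param alpha_flag Flag threshold on the p-value (default 0.003, the
#'   Bonferroni-style criterion used with 17 items).
#' @return A data frame with one row per item: `statistic`, `df`, `p_value`,
#'   `flagged`.
#' @export
sx2_item_fit <- function(responses, bank, grid = quadrature_grid(),
                         min_expected = 1, alpha_flag = 0.003) {
  resp <- check_responses(responses, bank)
  if (any(is.na(resp))) stop("complete cases required", call. = FALSE)
  n <- nrow(resp)
  J <- length(bank)
  m <- n_categories(bank)
  total0 <- rowSums(resp) - J          # 0-based summed score
  Smax <- sum(m) - J
  w <- grid$weights
  full_dist <- summed_score_distribution(bank, grid$nodes)       # (Smax+1) x Q
  marg_total <- as.numeric(full_dist %*% w)

  out <- data.frame(item = item_ids(bank), statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, flagged = NA)
  for (i in seq_len(J)) {
    rest <- summed_score_distribution(bank, grid$nodes, items = setdiff(seq_len(J), i))
    P <- grm_cat_prob(bank$items[[i]], grid$nodes)               # m x Q
    # joint P(S = s, X_i = k) marginalized over the prior
    nS <- Smax + 1L
    joint <- matrix(0, nS, m[i])
    for (k in seq_len(m[i])) {
      shifted <- matrix(0, nS, length(w))
      rows <- seq_len(nrow(rest))
      shifted[rows + (k - 1L), ] <- rest
      joint[, k] <- (shifted * rep(P[k, ], each = nS)) %*% w
    }
    obs <- matrix(0, nS, m[i])
    for (k in seq_len(m[i]))
      obs[, k] <- tabulate(total0[resp[, i] == k] + 1L, nS)
    ns <- rowSums(obs)
    cond <- joint / pmax(rowSums(joint), 1e-300)                 # P(X_i = k | S = s)
    expd <- cond * ns
    fit <- collapse_and_chisq(obs, expd, min_expected)
    df <- max(1L, fit$cells - fit$groups - m[i])                 # m[i] = a + (m-1) b's
    out$statistic[i] <- fit$x2
    out$df[i] <- df
    out$p_value[i] <- stats::pchisq(fit$x2, df, lower.tail = FALSE)
  }
  out$flagged <- out$p_value < alpha_flag
  out
}

# merge adjacent summed-score rows until expected counts are large enough,
# then pool sparse categories within rows; returns the Pearson statistic and
# the cell/group counts used for df
collapse_and_chisq <- function(obs, expd, min_expected) {
  keep <- rowSums(obs) > 0
  obs <- obs[keep, , drop = FALSE]
  expd <- expd[keep, , drop = FALSE]
  # merge rows upward until min(E) >= min_expected and >= 80% of cells >= 5
  repeat {
    ok_min <- all(expd[expd > 0] >= min_expected)
    ok_five <- mean(expd[expd > 0] >= 5) >= 0.8
    if ((ok_min && ok_five) || nrow(obs) == 1L) break
    rmins <- apply(expd, 1, function(e) min(e[e > 0]))
    r <- which.min(rmins)
    nb <- if (r == 1L) 2L else if (r == nrow(obs)) r - 1L else
      if (rmins[r - 1] < rmins[r + 1]) r - 1L else r + 1L
    obs[nb, ] <- obs[nb, ] + obs[r, ]
    expd[nb, ] <- expd[nb, ] + expd[r, ]
    obs <- obs[-r, , drop = FALSE]
    expd <- expd[-r, , drop = FALSE]
  }
  x2 <- 0; cells <- 0L
  for (r in seq_len(nrow(obs))) {
    o <- obs[r, ]; e <- expd[r, ]
    # pool categories with tiny expecteds into the nearest non-tiny neighbor
    while (any(e < min_expected & e >= 0) && length(e) > 1L) {
      k <- which.min(e)
      nb <- if (k == 1L) 2L else if (k == length(e)) k - 1L else
        if (e[k - 1] < e[k + 1]) k - 1L else k + 1L
      o[nb] <- o[nb] + o[k]; e[nb] <- e[nb] + e[k]
      o <- o[-k]; e <- e[-k]
    }
    x2 <- x2 + sum((o - e)^2 / e)
    cells <- cells + length(e)
  }
  list(x2 = x2, cells = cells, groups = nrow(obs))
}

#' DIF screening by ordinal logistic regression
#'
#' For each item, nested proportional-odds models are fitted by maximum
#' likelihood: a base model regressing the item response on the matching
#' variable (the full-pattern EAP estimate) and an augmented model adding the
#' group main effect and its interaction with the matching variable (uniform
#' plus non-uniform DIF). The effect size is McFadden's pseudo-R-squared
#' change, `(llA - ll0) / (-ll_null)`; items at or above `flag_threshold`
#' (2%) are flagged.
#'
#' @param responses Complete integer response matrix.
#' @param group Binary group labels (factor, character or numeric), one per
#'   respondent; both groups must have at least 2 members.
#' @param bank Calibrated `item_bank` (supplies the EAP matching variable).
#' @param grid A [quadrature_grid()].
#' @param flag_threshold Pseudo-R-squared change flagged as DIF (default 0.02).
#' @return A data frame with one row per item: `r2_change`, `flagged`; items
#'   the models could not be fitted for (e.g. separation) carry `NA` and a
#'   warning is issued.
#' @export
dif_scan <- function(responses, group, bank, grid = quadrature_grid(),
                     flag_threshold = 0.02) {
  resp <- check_responses(responses, bank)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must be binary", call. = FALSE)
  if (any(table(group) < 2L)) stop("each group needs at least 2 members", call. = FALSE)
  post <- eap_from_loglik(loglik_matrix(resp, node_logprobs(bank, grid)), grid)
  theta <- post$theta
  out <- data.frame(item = item_ids(bank), r2_change = NA_real_, flagged = NA)
  for (i in seq_len(ncol(resp))) {
    d <- data.frame(y = factor(resp[, i], ordered = TRUE), theta = theta, g = group)
    fits <- tryCatch({
      ll_null <- as.numeric(stats::logLik(MASS::polr(y ~ 1, data = d)))
      ll0 <- as.numeric(stats::logLik(MASS::polr(y ~ theta, data = d)))
      llA <- as.numeric(stats::logLik(MASS::polr(y ~ theta * g, data = d)))
      (max(llA, ll0) - ll0) / (-ll_null)   # nested: negative slack is numerical
    }, error = function(e) {
      warning("item ", item_ids(bank)[i], " skipped: ", conditionMessage(e))
      NA_real_
    })
    out$r2_change[i] <- fits
  }
  out$flagged <- out$r2_change >= flag_threshold
  out
}

#' Modal-category diagnostic for disordered thresholds
#'
#' A response category that is never the most probable one at any latent value
#' signals closely spaced (effectively disordered) thresholds: the category's
#' probability curve is dominated everywhere. The scan evaluates the category
#' curves on a theta grid and reports, per item, the categories that are never
#' modal.
#'
#' @param bank An `item_bank`.
#' @param theta_range Evaluation range (default `[-6, 6]`).
#' @param step Grid step (default 0.01).
#' @return An object of class `modal_check`: named list `never_modal` (integer
#'   vector per item, possibly empty) and `flagged_items` (ids of items with
#'   at least one never-modal category).
#' @export
modal_category_check <- function(bank, theta_range = c(-6, 6), step = 0.01) {
  thetas <- seq(theta_range[1], theta_range[2], by = step)
  ids <- item_ids(bank)
  never <- lapply(bank$items, function(it) {
    P <- grm_cat_prob(it, thetas)
    modal <- max.col(t(P), ties.method = "first")
    setdiff(seq_len(nrow(P)), unique(modal))
  })
  names(never) <- ids
  structure(list(never_modal = never,
                 flagged_items = ids[lengths(never) > 0]),
            class = "modal_check")
}

#' @export
print.modal_check <- function(x, ...) {
  nf <- length(x$flagged_items)
  cat(sprintf("Modal-category scan: %d item%s with never-modal categories\n",
              nf, if (nf == 1) "" else "s"))
  for (id in x$flagged_items)
    cat(sprintf("  %s: categories %s\n", id,
                paste(x$never_modal[[id]], collapse = ", ")))
  invisible(x)
}
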