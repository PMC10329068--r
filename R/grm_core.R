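#' Cumulative category probabilities of a graded item
#'
#' Under the graded response model the probability of responding in category
#' `k` or higher follows a two-parameter logistic curve,
#' `P*_k(theta) = 1 / (1 + exp(-a (theta - b_k)))`, `k = 1..m-1`. The curves
#' share the item slope and are strictly ordered because the thresholds are.
#'
#' @param item A [graded_item()].
#' @param theta Numeric vector of latent trait values.
#' @return Matrix with `m - 1` rows (one per boundary) and `length(theta)`
#'   columns.
#' @export
grm_cum_prob <- function(item, theta) {
  out <- stats::plogis(item$a * outer(item$b, theta, function(b, t) t - b))
  dimnames(out) <- NULL
  matrix(out, nrow = length(item$b))
}

#' Category probabilities of a graded item
#'
#' Adjacent differences of the cumulative curves: `P_k = P*_{k-1} - P*_k` with
#' `P*_0 = 1` and `P*_m = 0`. At every finite theta the result is a strict
#' probability simplex over the `m` categories.
#'
#' @inheritParams grm_cum_prob
#' @return Matrix with `m` rows (categories `1..m`) and `length(theta)`
#'   columns; columns sum to 1.
#' @export
grm_cat_prob <- function(item, theta) {
  ps <- grm_cum_prob(item, theta)
  nt <- ncol(ps)
  full <- rbind(rep(1, nt), ps, rep(0, nt))
  full[seq_len(nrow(ps) + 1L), , drop = FALSE] -
    full[seq_len(nrow(ps) + 1L) + 1L, , drop = FALSE]
}

#' Fisher information of a graded item
#'
#' `I(theta) = sum_k P'_k(theta)^2 / P_k(theta)` where
#' `P'_k = a (P*_{k-1} Q*_{k-1} - P*_k Q*_k)` is the derivative of the category
#' probability. For a two-category item this reduces to the familiar
#' `a^2 P Q`.
#'
#' @inheritParams grm_cum_prob
#' @return Nonnegative numeric vector, one value per theta.
#' @export
item_information <- function(item, theta) {
  ps <- grm_cum_prob(item, theta)
  nt <- ncol(ps)
  full <- rbind(rep(1, nt), ps, rep(0, nt))
  d <- item$a * full * (1 - full)
  k <- seq_len(nrow(ps) + 1L)
  P <- full[k, , drop = FALSE] - full[k + 1L, , drop = FALSE]
  dP <- d[k, , drop = FALSE] - d[k + 1L, , drop = FALSE]
  contrib <- dP * dP / P
  contrib[P <= 0] <- 0   # categories underflowing to zero mass in deep tails
  colSums(contrib)
}

#' Test information of a bank
#'
#' Fisher informations are additive over locally independent items, so the
#' test information is the sum of the item informations. The standard error of
#' a maximum-likelihood trait estimate is approximately `1/sqrt(I(theta))`;
#' test information of 10 corresponds to marginal reliability of about 0.9.
#'
#' @param bank An `item_bank`.
#' @param theta Numeric vector of latent trait values.
#' @return Numeric vector, one value per theta.
#' @export
test_information <- function(bank, theta) {
  if (length(bank) == 0L) {
    warning("empty bank: test information is 0")
    return(rep(0, length(theta)))
  }
  Reduce(`+`, lapply(bank$items, item_information, theta = theta))
}

#' Model-expected raw sum score (test characteristic curve)
#'
#' `E[S | theta] = sum_i sum_k k P_ik(theta)` with categories coded `1..m_i`;
#' strictly increasing in theta, with limits `S_min` and `S_max`.
#'
#' @inheritParams test_information
#' @return Numeric vector of expected sum scores.
#' @export
expected_sum_score <- function(bank, theta) {
  Reduce(`+`, lapply(bank$items, function(it) {
    P <- grm_cat_prob(it, theta)
    colSums(P * seq_len(nrow(P)))
  }))
}

#' Linear 0-100 scale transform of a raw sum score
#'
#' Maps the raw sum score `s` in `[S_min, S_max]` linearly onto 0-100 with the
#' orientation reversed: `100 (S_max - s) / (S_max - S_min)`, so the all-lowest
#' pattern (no limitations) scores 100 and the all-highest pattern scores 0.
#'
#' @param s Numeric vector of raw sum scores (may be model-expected,
#'   non-integer values).
#' @param bank The `item_bank` defining `S_min` and `S_max`.
#' @return Numeric vector on the 0-100 metric, higher = fewer limitations.
#' @export
scale_score <- function(s, bank) {
  rng <- sum_score_range(bank)
  if (any(s < rng["s_min"] - 1e-9 | s > rng["s_max"] + 1e-9, na.rm = TRUE))
    stop("sum score outside [", rng["s_min"], ", ", rng["s_max"], "]",
         call. = FALSE)
  unname(100 * (rng["s_max"] - s) / (rng["s_max"] - rng["s_min"]))
}

#' Simulate response patterns from a bank
#'
#' Draws each response independently from the item's category distribution at
#' the respondent's latent value.
#'
#' @param bank An `item_bank`.
#' @param theta Numeric vector of true latent values, one per respondent.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer matrix (`length(theta)` x `length(bank)`) of category codes
#'   `1..m_i`, with item ids as column names.
#' @export
simulate_responses <- function(bank, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(theta)
  out <- matrix(NA_integer_, n, length(bank),
                dimnames = list(NULL, item_ids(bank)))
  for (i in seq_along(bank$items)) {
    P <- grm_cat_prob(bank$items[[i]], theta)   # m x n
    cum <- apply(P, 2, cumsum)
    cum[nrow(P), ] <- 1  # guard against cumulative rounding at the top category
    u <- stats::runif(n)
    out[, i] <- 1L + colSums(cum < rep(u, each = nrow(P)))
  }
  out
}
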