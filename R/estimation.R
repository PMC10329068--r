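#' Quadrature grid for latent-trait integration
#'
#' Equally spaced nodes with weights proportional to the standard-normal
#' density, renormalized to sum to one. This realizes the N(0,1) latent
#' calibration used both as EAP prior and as the marginal distribution in EM
#' calibration. The default (61 nodes on `[-6, 6]`) matches the convention of
#' the estimation software family this engine mirrors; the wide range matters
#' for extreme response patterns, whose posterior mean would otherwise be
#' truncated at the grid bound.
#'
#' @param lower,upper Grid bounds on the latent metric.
#' @param n Number of nodes.
#' @param mean,sd Prior mean and standard deviation.
#' @return An object of class `quadrature_grid` with fields `nodes` and
#'   `weights`.
#' @export
quadrature_grid <- function(lower = -6, upper = 6, n = 61, mean = 0, sd = 1) {
  nodes <- seq(lower, upper, length.out = n)
  w <- stats::dnorm(nodes, mean, sd)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "quadrature_grid")
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("<quadrature_grid> %d nodes on [%g, %g]\n",
              length(x$nodes), min(x$nodes), max(x$nodes)))
  invisible(x)
}

# per-item log category probabilities at the grid nodes: list of m x Q matrices
node_logprobs <- function(bank, grid) {
  lapply(bank$items, function(it) log(grm_cat_prob(it, grid$nodes)))
}

# n x Q log-likelihood matrix of (possibly partial) response rows
loglik_matrix <- function(resp, lpn) {
  n <- nrow(resp); Q <- ncol(lpn[[1]])
  ll <- matrix(0, n, Q)
  for (i in seq_along(lpn)) {
    x <- resp[, i]
    ok <- which(!is.na(x))
    if (length(ok)) ll[ok, ] <- ll[ok, ] + lpn[[i]][x[ok], , drop = FALSE]
  }
  ll
}

# posterior mean and SD per row of a log-likelihood matrix
eap_from_loglik <- function(ll, grid) {
  lp <- sweep(ll, 2, log(grid$weights), `+`)
  mx <- apply(lp, 1, max)
  p <- exp(lp - mx)
  p <- p / rowSums(p)
  theta <- as.numeric(p %*% grid$nodes)
  second <- as.numeric(p %*% (grid$nodes^2))
  se <- sqrt(pmax(second - theta^2, 0))
  list(theta = theta, se = se)
}

check_responses <- function(resp, bank) {
  resp <- as.matrix(resp)
  if (ncol(resp) != length(bank))
    stop("response matrix has ", ncol(resp), " columns for a bank of ",
         length(bank), " items", call. = FALSE)
  m <- n_categories(bank)
  for (i in seq_len(ncol(resp))) {
    x <- resp[, i]
    bad <- which(!is.na(x) & (x < 1 | x > m[i] | x != round(x)))
    if (length(bad))
      stop("invalid response category for item '", item_ids(bank)[i],
           "' (rows ", paste(utils::head(bad, 3), collapse = ", "),
           "): categories are 1..", m[i], call. = FALSE)
  }
  storage.mode(resp) <- "integer"
  resp
}

#' EAP latent-trait estimate for one response pattern
#'
#' Expected a posteriori scoring: the posterior mean of theta under a standard
#' normal prior evaluated on a quadrature grid, with the posterior standard
#' deviation reported as the standard error. Unanswered items (`NA`) are
#' ignored; with no responses at all the posterior equals the prior.
#'
#' @param bank An `item_bank`.
#' @param responses Integer vector of category codes (`1..m_i`) of length
#'   `length(bank)`, `NA` for unanswered items.
#' @param grid A [quadrature_grid()].
#' @return An object of class `theta_estimate`: fields `theta`, `se`, `method`
#'   and `n_items`.
#' @examples
#' est <- eap_estimate(aaq_bank(), rep(1L, 17))
#' est$theta
#' @export
eap_estimate <- function(bank, responses, grid = quadrature_grid()) {
  resp <- check_responses(matrix(as.integer(responses), nrow = 1), bank)
  ll <- loglik_matrix(resp, node_logprobs(bank, grid))
  post <- eap_from_loglik(ll, grid)
  structure(list(theta = post$theta, se = post$se, method = "EAP",
                 n_items = sum(!is.na(responses))),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("<theta_estimate> theta = %.3f (se = %.3f), %s on %d item%s\n",
              x$theta, x$se, x$method, x$n_items, if (x$n_items == 1) "" else "s"))
  invisible(x)
}

#' Score respondents on the original and IRT 0-100 metrics
#'
#' For each row of a response matrix computes (i) the original scale score:
#' the linear 0-100 transform of the raw sum score, defined for complete
#' patterns only; and (ii) the model-based score: EAP theta mapped through the
#' expected sum score of the full bank and the same 0-100 transform, defined
#' for partial patterns too. Respondents with no responses at all are flagged
#' and left unscored.
#'
#' @param bank An `item_bank`.
#' @param responses Integer matrix, respondents x items, categories `1..m_i`,
#'   `NA` for missing.
#' @param grid A [quadrature_grid()].
#' @return A data frame with one row per respondent: `n_answered`,
#'   `sum_score`, `original_0_100`, `theta`, `se`, `irt_0_100`.
#' @export
score_respondents <- function(bank, responses, grid = quadrature_grid()) {
  resp <- check_responses(responses, bank)
  n_answered <- rowSums(!is.na(resp))
  if (any(n_answered == 0L))
    warning(sum(n_answered == 0L), " respondent(s) with no responses left unscored")
  post <- eap_from_loglik(loglik_matrix(resp, node_logprobs(bank, grid)), grid)
  sum_score <- ifelse(n_answered == length(bank), rowSums(resp), NA_real_)
  out <- data.frame(
    n_answered = n_answered,
    sum_score = sum_score,
    original_0_100 = ifelse(is.na(sum_score), NA_real_, scale_score(
      ifelse(is.na(sum_score), sum_score_range(bank)["s_min"], sum_score), bank)),
    theta = ifelse(n_answered > 0L, post$theta, NA_real_),
    se = ifelse(n_answered > 0L, post$se, NA_real_))
  out$irt_0_100 <- ifelse(n_answered > 0L,
                          scale_score(expected_sum_score(bank, out$theta), bank),
                          NA_real_)
  rn <- rownames(responses)
  out <- cbind(respondent = if (is.null(rn)) seq_len(nrow(out)) else rn, out)
  rownames(out) <- NULL
  out
}

#' Control parameters for GRM calibration
#'
#' @param max_cycles Maximum EM cycles.
#' @param tol Convergence criterion: maximum absolute change of any item
#'   parameter between cycles.
#' @param verbose Print the log-likelihood each cycle.
#' @return A list of class `grm_control`.
#' @export
grm_control <- function(max_cycles = 500L, tol = 1e-4, verbose = FALSE) {
  structure(list(max_cycles = as.integer(max_cycles), tol = tol,
                 verbose = isTRUE(verbose)), class = "grm_control")
}

# (a, b) <-> unconstrained (log a, b1, log spacings): keeps a > 0 and the
# thresholds strictly ordered during optimization
pars_to_free <- function(a, b) {
  c(log(a), b[1], if (length(b) > 1) log(diff(b)))
}
free_to_pars <- function(free) {
  a <- exp(free[1])
  b <- cumsum(c(free[2], if (length(free) > 2) exp(free[-(1:2)])))
  list(a = a, b = b)
}

item_start_values <- function(x, m) {
  p <- tabulate(x[!is.na(x)], m) / sum(!is.na(x))
  cum_le <- cumsum(p)[seq_len(m - 1L)]                 # P(X <= k)
  b <- stats::qlogis(pmin(pmax(cum_le, 0.01), 0.99))
  # enforce a minimal spacing so the log-spacing parameterization is finite
  for (k in seq_along(b)[-1]) b[k] <- max(b[k], b[k - 1] + 0.05)
  list(a = 1.5, b = b)
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' Calibrates a polytomous item bank from a respondent-by-item matrix of
#' ordered category codes using the EM algorithm: the E-step computes each
#' respondent's posterior over a fixed N(0,1) quadrature grid (which also
#' identifies the latent metric), the M-step refits each item's slope and
#' thresholds against the expected category-by-node counts by quasi-Newton
#' search on an unconstrained parameterization (log slope, first threshold,
#' log threshold spacings), which enforces threshold ordering by construction.
#' Missing responses are treated as ignorable and simply drop out of the
#' respondent's likelihood.
#'
#' @param responses Integer matrix (respondents x items), categories `1..m_i`,
#'   `NA` for missing. Every category of every item must be observed at least
#'   once; otherwise collapse categories first (see [collapse_categories()]).
#' @param n_categories Optional integer vector of category counts per item;
#'   defaults to the maximum observed code.
#' @param grid A [quadrature_grid()].
#' @param control A [grm_control()].
#' @return An object of class `grm`: fields `bank` (the calibrated
#'   [item_bank()]), `loglik` (marginal log-likelihood trace, non-decreasing),
#'   `converged`, `cycles`, `n`. Methods: `print`, `summary`, `coef`,
#'   `logLik`.
#' @examples
#' \donttest{
#' bank <- aaq_bank()
#' x <- simulate_responses(bank, rnorm(500), seed = 1)
#' fit <- grm(x, control = grm_control(max_cycles = 50, tol = 1e-3))
#' coef(fit)
#' }
#' @export
grm <- function(responses, n_categories = NULL, grid = quadrature_grid(),
                control = grm_control()) {
  resp <- as.matrix(responses)
  storage.mode(resp) <- "integer"
  n <- nrow(resp); J <- ncol(resp)
  m <- if (is.null(n_categories)) apply(resp, 2, max, na.rm = TRUE)
       else as.integer(n_categories)
  if (any(m < 2L)) stop("every item needs at least 2 observed categories", call. = FALSE)
  for (i in seq_len(J)) {
    seen <- tabulate(resp[!is.na(resp[, i]), i], m[i])
    if (any(seen == 0L))
      stop("item ", i, ": categories ", paste(which(seen == 0L), collapse = ", "),
           " unobserved; collapse categories before calibration", call. = FALSE)
  }
  if (n < 10 * J)
    warning("only ", n, " respondents for ", J,
            " items; calibration may be unstable")
  ids <- colnames(resp)
  if (is.null(ids)) ids <- sprintf("item_%02d", seq_len(J))

  pars <- lapply(seq_len(J), function(i) item_start_values(resp[, i], m[i]))
  Q <- length(grid$nodes)
  trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  lw <- log(grid$weights)

  neg_expected_ll <- function(free, R, nodes) {
    if (any(!is.finite(free)) || free[1] > 5) return(1e10)
    p <- free_to_pars(free)
    lp <- log(pmax(grm_cat_prob(list(a = p$a, b = p$b), nodes), 1e-300))
    -sum(R * lp)
  }

  while (cycle < control$max_cycles) {
    cycle <- cycle + 1L
    # E-step
    lpn <- lapply(seq_len(J), function(i)
      log(pmax(grm_cat_prob(list(a = pars[[i]]$a, b = pars[[i]]$b), grid$nodes),
               1e-300)))
    ll <- loglik_matrix(resp, lpn)
    lj <- sweep(ll, 2, lw, `+`)
    mx <- apply(lj, 1, max)
    post <- exp(lj - mx)
    norm <- rowSums(post)
    trace <- c(trace, sum(log(norm) + mx))
    if (control$verbose)
      message(sprintf("cycle %d: logLik %.4f", cycle, trace[cycle]))
    post <- post / norm
    # M-step, item by item
    old <- pars
    for (i in seq_len(J)) {
      x <- resp[, i]
      ok <- !is.na(x)
      R <- rowsum(post[ok, , drop = FALSE], group = factor(x[ok], levels = seq_len(m[i])))
      opt <- stats::optim(pars_to_free(pars[[i]]$a, pars[[i]]$b),
                          neg_expected_ll, R = R, nodes = grid$nodes,
                          method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-10))
      pars[[i]] <- free_to_pars(opt$par)
    }
    delta <- max(vapply(seq_len(J), function(i)
      max(abs(c(pars[[i]]$a - old[[i]]$a, pars[[i]]$b - old[[i]]$b))), 0))
    if (delta < control$tol) { converged <- TRUE; break }
  }

  items <- lapply(seq_len(J), function(i)
    graded_item(ids[i], a = pars[[i]]$a, b = pars[[i]]$b))
  structure(list(bank = item_bank(items, name = "calibrated"),
                 loglik = trace, converged = converged, cycles = cycle,
                 n = n, grid = grid, call = match.call()),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Graded response model: %d items, %d respondents\n",
              length(x$bank), x$n))
  cat(sprintf("  EM %s after %d cycles, logLik %.2f\n",
              if (x$converged) "converged" else "did NOT converge",
              x$cycles, x$loglik[length(x$loglik)]))
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) {
  m <- n_categories(object$bank)
  nb <- max(m) - 1L
  out <- t(vapply(object$bank$items, function(it)
    c(it$a, it$b, rep(NA_real_, nb - length(it$b))), numeric(nb + 1L)))
  dimnames(out) <- list(item_ids(object$bank), c("a", paste0("b", seq_len(nb))))
  out
}

#' @export
logLik.grm <- function(object, ...) {
  val <- object$loglik[length(object$loglik)]
  npar <- sum(n_categories(object$bank))  # one slope + (m-1) thresholds per item
  structure(val, df = npar, nobs = object$n, class = "logLik")
}

#' @export
summary.grm <- function(object, ...) {
  structure(list(coef = coef(object), converged = object$converged,
                 cycles = object$cycles, n = object$n,
                 loglik = object$loglik[length(object$loglik)]),
            class = "summary.grm")
}

#' @export
print.summary.grm <- function(x, ...) {
  cat(sprintf("GRM calibration (n = %d): logLik %.2f, %d cycles%s\n",
              x$n, x$loglik, x$cycles,
              if (x$converged) "" else " (not converged)"))
  print(round(x$coef, 3))
  invisible(x)
}
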