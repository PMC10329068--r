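#' CAT stopping rule
#'
#' A session ends as soon as the EAP posterior standard error drops to the
#' threshold or below (checked after each response once `min_items` have been
#' administered), or when `max_items` have been given. The bank versions
#' studied with the bundled AAQ bank are caps of 17, 10 and 5 items with
#' `se_threshold = 0.3` (marginal reliability about 0.9).
#'
#' @param se_threshold Positive standard-error threshold (default 0.3).
#' @param max_items Maximum number of items to administer.
#' @param min_items Minimum number of items before the SE rule applies
#'   (default 1, i.e. no forced minimum).
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(se_threshold = 0.3, max_items, min_items = 1L) {
  stopifnot(se_threshold > 0, min_items >= 1L, min_items <= max_items)
  structure(list(se_threshold = se_threshold, max_items = as.integer(max_items),
                 min_items = as.integer(min_items)), class = "stopping_rule")
}

#' @export
print.stopping_rule <- function(x, ...) {
  cat(sprintf("<stopping_rule> stop at se <= %g, items in [%d, %d]\n",
              x$se_threshold, x$min_items, x$max_items))
  invisible(x)
}

#' Response providers for CAT sessions
#'
#' A response provider is a function that, asked for an item index, returns
#' that respondent's category. `pattern_provider` replays a stored complete
#' pattern (post-hoc simulation mode); `simulee_provider` draws a full pattern
#' from the graded response model at a true latent value when constructed
#' (seeded, hence reproducible) and then replays it, so both modes share one
#' administration path.
#'
#' @param pattern Integer vector of category codes covering the whole bank.
#' @return A function `f(item_index) -> category`.
#' @export
pattern_provider <- function(pattern) {
  pattern <- as.integer(pattern)
  if (anyNA(pattern)) stop("post-hoc mode requires a complete pattern", call. = FALSE)
  function(i) pattern[i]
}

#' @rdname pattern_provider
#' @param bank An `item_bank`.
#' @param theta True latent value of the simulee.
#' @param seed Optional integer seed.
#' @export
simulee_provider <- function(bank, theta, seed = NULL) {
  pattern_provider(drop(simulate_responses(bank, theta, seed = seed)))
}

#' Select the next item by maximum Fisher information
#'
#' Returns the unadministered item with the largest Fisher information at the
#' current trait estimate; ties are broken by bank order.
#'
#' @param bank An `item_bank`.
#' @param administered Integer vector of already administered item indices.
#' @param theta Current trait estimate (scalar).
#' @return The selected item index.
#' @export
select_next_item <- function(bank, administered, theta) {
  remaining <- setdiff(seq_len(length(bank)), administered)
  if (length(remaining) == 0L) stop("all items administered", call. = FALSE)
  info <- vapply(remaining, function(i)
    item_information(bank$items[[i]], theta), 0)
  remaining[which.max(info)]   # which.max takes the first maximum: bank order
}

# one adaptive session against a complete pattern, using precomputed node
# log-probabilities (shared by run_cat and run_cohort so the two cannot drift)
cat_session <- function(bank, lpn, elicit, rule, start_theta, grid) {
  J <- length(bank)
  lw <- log(grid$weights)
  lp <- lw
  administered <- integer(0)
  responses <- integer(0)
  theta <- start_theta
  traj_theta <- numeric(0)
  traj_se <- numeric(0)
  stop_reason <- NA_character_
  repeat {
    sel <- select_next_item(bank, administered, theta)
    x <- elicit(sel)
    administered <- c(administered, sel)
    responses <- c(responses, x)
    lp <- lp + lpn[[sel]][x, ]
    p <- exp(lp - max(lp)); p <- p / sum(p)
    theta <- sum(p * grid$nodes)
    se <- sqrt(max(sum(p * grid$nodes^2) - theta^2, 0))
    traj_theta <- c(traj_theta, theta)
    traj_se <- c(traj_se, se)
    k <- length(administered)
    if (k >= rule$min_items && se <= rule$se_threshold) { stop_reason <- "se_met"; break }
    if (k >= rule$max_items) { stop_reason <- "max_items"; break }
    if (k >= J) { stop_reason <- "bank_exhausted"; break }
  }
  list(administered = administered, responses = responses,
       theta = traj_theta, se = traj_se, stop_reason = stop_reason)
}

#' Run one adaptive test session
#'
#' The administration loop: select the most informative unadministered item at
#' the current EAP estimate, elicit the response from the provider,
#' re-estimate theta (EAP on the administered items), then check the stopping
#' rule. The final 0-100 score maps the final theta through the full bank's
#' expected sum score and the linear scale transform.
#'
#' @param bank An `item_bank`.
#' @param provider A response provider, see [pattern_provider()].
#' @param rule A [stopping_rule()].
#' @param start_theta Starting trait estimate (default 0, the prior mean).
#' @param grid A [quadrature_grid()].
#' @return An object of class `cat_record`: administered item ids and
#'   responses, the per-step `(theta, se)` trajectory, stop reason (`se_met`,
#'   `max_items` or `bank_exhausted`), final `theta_estimate` and final
#'   `score_0_100`.
#' @examples
#' bank <- aaq_bank()
#' rec <- run_cat(bank, pattern_provider(rep(2L, 17)),
#'                stopping_rule(0.3, max_items = 17))
#' rec
#' @export
run_cat <- function(bank, provider, rule, start_theta = 0,
                    grid = quadrature_grid()) {
  stopifnot(inherits(rule, "stopping_rule"))
  if (rule$max_items > length(bank))
    stop("max_items exceeds bank size", call. = FALSE)
  lpn <- node_logprobs(bank, grid)
  s <- cat_session(bank, lpn, provider, rule, start_theta, grid)
  k <- length(s$administered)
  final <- structure(list(theta = s$theta[k], se = s$se[k], method = "EAP",
                          n_items = k), class = "theta_estimate")
  structure(list(
    item_ids = item_ids(bank)[s$administered],
    item_index = s$administered,
    responses = s$responses,
    trajectory = data.frame(step = seq_len(k), item = item_ids(bank)[s$administered],
                            theta = s$theta, se = s$se),
    stop_reason = s$stop_reason,
    final = final,
    score_0_100 = scale_score(expected_sum_score(bank, s$theta[k]), bank)),
    class = "cat_record")
}

#' @export
print.cat_record <- function(x, ...) {
  k <- length(x$item_ids)
  cat(sprintf("<cat_record> %d item%s, stop: %s\n", k, if (k == 1) "" else "s",
              x$stop_reason))
  cat("  sequence:", paste(x$item_ids, collapse = " "), "\n")
  cat(sprintf("  final theta %.3f (se %.3f), score %.1f/100\n",
              x$final$theta, x$final$se, x$score_0_100))
  invisible(x)
}

#' Run a CAT over a cohort
#'
#' Post-hoc mode replays the adaptive algorithm against stored complete
#' response patterns; simulee mode first draws full patterns from the bank at
#' supplied true theta values (seeded) and then proceeds identically.
#' Incomplete rows cannot be replayed post-hoc and are skipped with a warning.
#'
#' @param bank An `item_bank`.
#' @param responses Complete integer response matrix (post-hoc mode), or
#'   `NULL` when `thetas` is given.
#' @param thetas True latent values (simulee mode), or `NULL`.
#' @param rule A [stopping_rule()].
#' @param start_theta Starting estimate for every session.
#' @param grid A [quadrature_grid()].
#' @param seed Seed for simulee-mode response generation.
#' @return An object of class `cat_cohort`: `records`, a data frame with one
#'   row per respondent (`n_items`, `stop_reason`, `theta`, `se`,
#'   `score_0_100`), and `sequences`, the list of administered item index
#'   vectors.
#' @export
run_cohort <- function(bank, responses = NULL, thetas = NULL, rule,
                       start_theta = 0, grid = quadrature_grid(), seed = NULL) {
  if (is.null(responses)) {
    if (is.null(thetas)) stop("supply responses (post-hoc) or thetas (simulee)",
                              call. = FALSE)
    responses <- simulate_responses(bank, thetas, seed = seed)
  }
  stopifnot(inherits(rule, "stopping_rule"))
  if (rule$max_items > length(bank))
    stop("max_items exceeds bank size", call. = FALSE)
  resp <- check_responses(responses, bank)
  complete <- rowSums(is.na(resp)) == 0L
  if (!all(complete)) {
    warning(sum(!complete), " incomplete row(s) skipped in post-hoc mode")
    resp <- resp[complete, , drop = FALSE]
  }
  lpn <- node_logprobs(bank, grid)
  n <- nrow(resp)
  n_items <- integer(n); stop_reason <- character(n)
  theta <- numeric(n); se <- numeric(n)
  sequences <- vector("list", n)
  for (r in seq_len(n)) {
    row <- resp[r, ]
    s <- cat_session(bank, lpn, function(i) row[i], rule, start_theta, grid)
    k <- length(s$administered)
    n_items[r] <- k; stop_reason[r] <- s$stop_reason
    theta[r] <- s$theta[k]; se[r] <- s$se[k]
    sequences[[r]] <- s$administered
  }
  structure(list(
    records = data.frame(respondent = seq_len(n), n_items = n_items,
                         stop_reason = stop_reason, theta = theta, se = se,
                         score_0_100 = scale_score(expected_sum_score(bank, theta),
                                                   bank)),
    sequences = sequences, rule = rule, bank_size = length(bank)),
    class = "cat_cohort")
}

#' @export
print.cat_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("<cat_cohort> %d sessions (se <= %g, cap %d)\n", nrow(r),
              x$rule$se_threshold, x$rule$max_items))
  cat(sprintf("  test length mean %.2f (min %d, max %d); se_met in %.1f%%\n",
              mean(r$n_items), min(r$n_items), max(r$n_items),
              100 * mean(r$stop_reason == "se_met")))
  invisible(x)
}

#' Per-item exposure rates of a CAT cohort run
#'
#' The fraction of sessions in which each item was administered. Summed over
#' items, exposure rates equal the mean test length.
#'
#' @param cohort A `cat_cohort` from [run_cohort()].
#' @param bank The `item_bank` used (for item ids).
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
exposure_rates <- function(cohort, bank) {
  n <- length(cohort$sequences)
  counts <- tabulate(unlist(cohort$sequences), nbins = length(bank))
  stats::setNames(counts / n, item_ids(bank))
}
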