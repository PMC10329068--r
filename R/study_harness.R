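#' Generate a synthetic respondent cohort
#'
#' Draws true latent values from a normal distribution (standard normal by
#' default, matching the latent calibration of the bundled bank: trait mean 0,
#' SD 1 in the calibration sample) and full response patterns from the graded
#' response model. The default size of 1408 matches the calibration study.
#'
#' @param bank An `item_bank`.
#' @param n Number of respondents.
#' @param theta_mean,theta_sd Latent distribution parameters.
#' @param seed Integer seed; the cohort is fully reproducible from its config.
#' @return An object of class `synthetic_cohort`: `theta` (true values),
#'   `responses` (complete matrix), `original_0_100` (sum-score-based scale
#'   scores) and `config`.
#' @examples
#' cohort <- generate_cohort(aaq_bank(), n = 50, seed = 1)
#' head(cohort$original_0_100)
#' @export
generate_cohort <- function(bank, n = 1408, theta_mean = 0, theta_sd = 1,
                            seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rnorm(n, theta_mean, theta_sd)
  responses <- simulate_responses(bank, theta)
  structure(list(
    theta = theta, responses = responses,
    original_0_100 = scale_score(rowSums(responses), bank),
    config = list(n = n, theta_mean = theta_mean, theta_sd = theta_sd,
                  seed = seed)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, theta ~ N(%g, %g^2)%s\n",
              x$config$n, x$config$theta_mean, x$config$theta_sd,
              if (is.null(x$config$seed)) "" else paste0(", seed ", x$config$seed)))
  cat(sprintf("  original 0-100 score: mean %.1f (sd %.1f)\n",
              mean(x$original_0_100), stats::sd(x$original_0_100)))
  invisible(x)
}

#' Compare CAT versions against the full measure
#'
#' Runs a post-hoc CAT per stopping rule over a cohort of complete patterns
#' and summarizes each version the way adaptive-test evaluations are usually
#' tabled: test length (mean, min, max), 0-100 score distribution, RMSE and
#' bias against the sum-score-based original scores, Pearson correlation with
#' the original scores, per-item exposure rates, and conditional
#' test-length/SE profiles by score decile. A "full" row scores the complete
#' patterns by EAP without adaptation, for reference.
#'
#' @param cohort A `synthetic_cohort`, or a complete integer response matrix.
#' @param bank An `item_bank`.
#' @param rules List of [stopping_rule()]s; names become version labels.
#' @param grid A [quadrature_grid()].
#' @param criteria Optional data frame of external criterion columns (one row
#'   per respondent); Pearson and Spearman correlations with each version's
#'   scores are reported.
#' @return An object of class `study_report`: `table` (one row per version),
#'   `exposure` (items x versions), `profiles` (per-version decile profiles),
#'   `scores` (per-respondent score matrix) and `criterion_correlations`.
#' @export
compare_versions <- function(cohort, bank, rules, grid = quadrature_grid(),
                             criteria = NULL) {
  responses <- if (inherits(cohort, "synthetic_cohort")) cohort$responses
               else as.matrix(cohort)
  if (nrow(responses) < 2L) stop("need at least 2 respondents", call. = FALSE)
  if (any(is.na(responses))) stop("complete response rows required", call. = FALSE)
  if (is.null(names(rules)))
    names(rules) <- vapply(rules, function(r) paste0("CAT-", r$max_items), "")
  original <- scale_score(rowSums(responses), bank)

  full <- score_respondents(bank, responses, grid)
  versions <- list(full = list(scores = full$irt_0_100, n_items = rep(length(bank),
                   nrow(responses)), se = full$se, cohort_run = NULL))
  for (v in names(rules)) {
    run <- run_cohort(bank, responses = responses, rule = rules[[v]], grid = grid)
    versions[[v]] <- list(scores = run$records$score_0_100,
                          n_items = run$records$n_items,
                          se = run$records$se, cohort_run = run)
  }

  tab <- do.call(rbind, lapply(names(versions), function(v) {
    s <- versions[[v]]$scores
    d <- s - original
    data.frame(version = v,
               mean_items = mean(versions[[v]]$n_items),
               min_items = min(versions[[v]]$n_items),
               max_items = max(versions[[v]]$n_items),
               score_mean = mean(s), score_sd = stats::sd(s),
               score_min = min(s), score_max = max(s),
               rmse = sqrt(mean(d^2)), bias = mean(d),
               r_original = stats::cor(s, original))
  }))
  exposure <- vapply(names(rules), function(v)
    exposure_rates(versions[[v]]$cohort_run, bank), numeric(length(bank)))
  profiles <- lapply(names(rules), function(v)
    conditional_profiles(versions[[v]]$cohort_run))
  names(profiles) <- names(rules)
  crit <- NULL
  if (!is.null(criteria)) {
    crit <- do.call(rbind, lapply(names(versions), function(v)
      do.call(rbind, lapply(names(criteria), function(cn)
        data.frame(version = v, criterion = cn,
                   pearson = stats::cor(versions[[v]]$scores, criteria[[cn]],
                                        use = "complete.obs"),
                   spearman = stats::cor(versions[[v]]$scores, criteria[[cn]],
                                         method = "spearman",
                                         use = "complete.obs"))))))
  }
  structure(list(table = tab, exposure = exposure, profiles = profiles,
                 scores = cbind(original = original,
                                vapply(versions, `[[`, numeric(nrow(responses)),
                                       "scores")),
                 criterion_correlations = crit),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("CAT version comparison\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Conditional test-length and precision profiles
#'
#' Bins respondents into deciles of the version's estimated 0-100 score and
#' reports per-bin mean test length and mean posterior SE — the usual way to
#' show where on the scale an adaptive test measures efficiently.
#'
#' @param cohort_run A `cat_cohort` from [run_cohort()].
#' @param n_bins Number of score bins (default 10).
#' @return A data frame with one row per bin: score range, `n`, `mean_items`,
#'   `mean_se`.
#' @export
conditional_profiles <- function(cohort_run, n_bins = 10) {
  r <- cohort_run$records
  if (nrow(r) < n_bins) stop("fewer respondents than bins", call. = FALSE)
  # rank-based binning keeps bin populations within 1 of n/n_bins under ties
  bins <- ceiling(rank(r$score_0_100, ties.method = "first") * n_bins / nrow(r))
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bins == b
    data.frame(bin = b,
               score_min = min(r$score_0_100[sel]),
               score_max = max(r$score_0_100[sel]),
               n = sum(sel),
               mean_items = mean(r$n_items[sel]),
               mean_se = mean(r$se[sel]))
  }))
  out
}
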