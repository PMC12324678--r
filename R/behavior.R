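# Trajectory analytics: strategy (action-modality) proportions by
# destination type and visit history, log-steps-to-goal summaries with
# bootstrap intervals, and the quadratic performance-vs-strategy regression.
# All log transforms are natural logs. Mixed-effects and Bayesian model
# comparison are deliberately out of scope: the module emits tidy per-step
# and per-trial tables suitable for external statistics tooling.

#' Annotate trajectory steps with destination type and visit history
#'
#' Labels each effective move with the type of its destination cell
#' (`goal`, `landmark`, `non_landmark`) and whether that cell had been
#' occupied earlier in the same trial's navigation phase. Logs produced by
#' [evaluate()] already carry these labels; this re-derives them from raw
#' positions (and is checked against an independent scan in the tests).
#'
#' @param log Trajectory tibble with `trial`, `step`, `row`, `col` and a
#'   step-0 start row per trial.
#' @param map The trial's `grid_map`, or a list of maps indexed by trial.
#' @return The log with `dest_type` and `visited_before` (re)computed.
#' @export
annotate_steps <- function(log, map) {
  if (any(log$row < 0 | log$row > 7 | log$col < 0 | log$col > 7))
    stop("cell outside the 8x8 interior")
  one_map <- inherits(map, "grid_map")
  out <- lapply(split(log, log$trial), function(tr) {
    tr <- tr[order(tr$step), ]
    m <- if (one_map) map else map[[tr$trial[1]]]
    lm_set <- paste(m$landmarks[, "row"], m$landmarks[, "col"])
    n <- nrow(tr)
    dest <- rep(NA_character_, n); vis <- rep(NA, n)
    for (i in seq_len(n)) {
      if (tr$step[i] == 0) next
      key <- paste(tr$row[i], tr$col[i])
      dest[i] <- if (all(c(tr$row[i], tr$col[i]) == m$goal)) "goal"
        else if (key %in% lm_set) "landmark" else "non_landmark"
      vis[i] <- any(tr$row[seq_len(i - 1)] == tr$row[i] &
                    tr$col[seq_len(i - 1)] == tr$col[i])
    }
    tr$dest_type <- dest; tr$visited_before <- vis
    tr
  })
  dplyr::bind_rows(out)
}

#' Strategy-use proportions by destination type and visit history
#'
#' @param log Annotated trajectory tibble (step-0 rows are ignored).
#' @return List with `overall` (direction-use proportion), `by_cell`
#'   (tibble: destination type x visited-before, with step counts and
#'   direction-use proportion) and `n_steps`.
#' @export
strategy_proportions <- function(log) {
  steps <- log[!is.na(log$modality), ]
  if (nrow(steps) == 0L) stop("no steps to summarise")
  by_cell <- steps |>
    dplyr::count(.data$dest_type, .data$visited_before,
                 .data$modality) |>
    tidyr::pivot_wider(names_from = "modality", values_from = "n",
                       values_fill = 0L)
  for (col in c("direction", "state"))
    if (!col %in% names(by_cell)) by_cell[[col]] <- 0L
  by_cell$n <- by_cell$direction + by_cell$state
  by_cell$p_direction <- by_cell$direction / by_cell$n
  list(overall = mean(steps$modality == "direction"),
       by_cell = by_cell, n_steps = nrow(steps))
}

#' Log steps-to-goal summaries with bootstrap intervals
#'
#' Natural-log transforms the per-trial steps-to-goal, then reports the
#' group mean and a seeded percentile bootstrap 95% interval per group.
#'
#' @param trials Per-trial tibble with `steps_to_goal` and grouping columns.
#' @param grouping Character vector of grouping column names.
#' @param n_boot Bootstrap resamples. @param seed Bootstrap seed.
#' @export
steps_to_goal_stats <- function(trials, grouping = "condition",
                                n_boot = 10000L, seed = 1L) {
  zero <- trials$steps_to_goal == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-step trials (cannot log-transform)")
    trials <- trials[!zero, ]
  }
  set.seed(as.integer(seed))
  trials$log_steps <- log(trials$steps_to_goal)
  groups <- split(trials, trials[grouping], drop = TRUE)
  if (any(vapply(groups, nrow, 0L) < 1L)) stop("empty group")
  out <- lapply(groups, function(g) {
    x <- g$log_steps
    boots <- vapply(seq_len(n_boot),
                    function(i) mean(x[sample.int(length(x), replace = TRUE)]),
                    numeric(1))
    res <- g[1, grouping, drop = FALSE]
    res$n <- length(x)
    res$mean_log_steps <- mean(x)
    res$ci_lo <- unname(stats::quantile(boots, 0.025))
    res$ci_hi <- unname(stats::quantile(boots, 0.975))
    res
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}

#' Quadratic performance-vs-strategy regression
#'
#' Ordinary least squares of per-subject mean log steps-to-goal on linear
#' and quadratic terms of the subject's direction-use proportion. A
#' positive quadratic coefficient indicates the U-shape in which subjects
#' relying exclusively on either modality perform worse than those mixing
#' the two.
#'
#' @param p_direction Per-subject direction-use proportions.
#' @param mean_log_steps Per-subject mean log steps-to-goal.
#' @return List `fit` (the `lm` object) and `coefficients` (tidy tibble
#'   with estimates, standard errors, t and p values).
#' @export
quadratic_performance_fit <- function(p_direction, mean_log_steps) {
  stopifnot(length(p_direction) == length(mean_log_steps))
  if (length(p_direction) < 4L) stop("need at least 4 subjects")
  fit <- stats::lm(mean_log_steps ~ p_direction + I(p_direction^2))
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient quadratic fit")
  sm <- summary(fit)$coefficients
  list(fit = fit,
       coefficients = tibble::tibble(
         term = c("intercept", "linear", "quadratic"),
         estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
         t_value = unname(sm[, 3]), p_value = unname(sm[, 4])))
}
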