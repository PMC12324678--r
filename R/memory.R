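# Simulated spatial memory: the agent enters the navigation phase with noisy
# coordinate estimates for the goal and each landmark, replacing an explicit
# map-reading phase. Noise magnitudes are calibrated to human memory-probe
# errors: the goal s.d. is drawn per trial from N(0.91, 0.44); the landmark
# s.d. follows s = m * log(n_exposures) + c with per-participant slope
# m ~ N(-0.63, 0.34) and intercept c ~ N(1.90, 0.60). All s.d. draws are
# floored at zero (a negative s.d. is undefined; the floor shifts the goal
# mean by < 0.005).

#' Noise-model parameter defaults
#'
#' @param goal_mean,goal_sd Mean and s.d. of the per-trial goal-noise draw.
#' @param m_mean,m_sd Slope distribution of noise vs log exposures.
#' @param c_mean,c_sd Intercept distribution (grid units).
#' @param log_base Base of the exposure logarithm (natural log by default).
#' @export
memory_noise_params <- function(goal_mean = 0.91, goal_sd = 0.44,
                                m_mean = -0.63, m_sd = 0.34,
                                c_mean = 1.90, c_sd = 0.60,
                                log_base = exp(1)) {
  list(goal_mean = goal_mean, goal_sd = goal_sd,
       m_mean = m_mean, m_sd = m_sd, c_mean = c_mean, c_sd = c_sd,
       log_base = log_base)
}

#' Draw one per-trial goal-noise standard deviation
#'
#' A single draw from N(0.91, 0.44), floored at 0.
#' @param params A [memory_noise_params()] list.
#' @export
draw_goal_noise <- function(params = memory_noise_params()) {
  max(0, stats::rnorm(1, params$goal_mean, params$goal_sd))
}

#' Draw one participant's landmark-noise slope and intercept
#'
#' Independent draws m ~ N(-0.63, 0.34) and c ~ N(1.90, 0.60); fixed across
#' a participant's (or agent batch's) trials within a session.
#' @param params A [memory_noise_params()] list.
#' @return Named numeric vector `c(m = , c = )`.
#' @export
draw_landmark_noise_params <- function(params = memory_noise_params()) {
  c(m = stats::rnorm(1, params$m_mean, params$m_sd),
    c = stats::rnorm(1, params$c_mean, params$c_sd))
}

#' Landmark noise s.d. as a function of exposure count
#'
#' `s = m * log(n_exposures) + c`, floored at 0. With the typical negative
#' slope, better-learnt (more exposed) landmarks are remembered more
#' precisely.
#' @param m,c Slope and intercept. @param n_exposures Exposure count (>= 1).
#' @param log_base Base of the logarithm.
#' @export
landmark_noise_sd <- function(m, c, n_exposures, log_base = exp(1)) {
  if (any(n_exposures < 1)) stop("n_exposures must be >= 1")
  pmax(0, m * log(n_exposures, base = log_base) + c)
}

#' Corrupt true coordinates with independent Gaussian noise
#'
#' Each coordinate receives an independent N(0, s) error; estimates stay
#' continuous (never rounded or clipped to the lattice).
#' @param true_xy Numeric length-2 (x, y). @param s Noise s.d. (>= 0).
#' @export
corrupt_coordinates <- function(true_xy, s) {
  stopifnot(s >= 0)
  true_xy + stats::rnorm(2, 0, s)
}

#' Build a trial's memory store
#'
#' Draws the per-trial goal noise, applies the participant-level (m, c)
#' landmark-noise law to each landmark's exposure count, and corrupts every
#' item's true (x, y) = (col, row). Identities without an item (including the
#' wall/obstacle sentinel 65) read back as the all-zero "no memory" sentinel.
#' The confidence entry of each item is the s.d. actually used.
#'
#' @param map A `grid_map`. @param mc Named vector `c(m = , c = )` from
#'   [draw_landmark_noise_params()].
#' @param params A [memory_noise_params()] list.
#' @param s_goal Optional fixed goal s.d. (drawn per trial when `NULL`).
#' @return A `memory_store`: 65 x 3 matrix (`est_x`, `est_y`, `sd`) indexed
#'   by state identity, with the item table as attribute `items`.
#' @export
build_memory_store <- function(map, mc = draw_landmark_noise_params(params),
                               params = memory_noise_params(), s_goal = NULL) {
  store <- matrix(0, nrow = 65, ncol = 3,
                  dimnames = list(NULL, c("est_x", "est_y", "sd")))
  if (is.null(s_goal)) s_goal <- draw_goal_noise(params)
  items <- list()

  add_item <- function(cell, s) {
    id <- map$identity[cell[1] + 1L, cell[2] + 1L]
    est <- corrupt_coordinates(c(cell[2], cell[1]), s)  # (x, y) = (col, row)
    store[id, ] <<- c(est, s)
    items[[length(items) + 1L]] <<- list(id = id, cell = cell, est = est, sd = s)
  }

  add_item(map$goal, s_goal)
  for (i in seq_len(nrow(map$landmarks))) {
    s <- landmark_noise_sd(mc[["m"]], mc[["c"]],
                           map$landmarks[i, "n_exposures"], params$log_base)
    add_item(map$landmarks[i, c("row", "col")], s)
  }
  structure(store, items = items, s_goal = s_goal, class = "memory_store")
}

#' Recall a state's remembered coordinates
#'
#' @param identity State identity in 1..65.
#' @param store A `memory_store`.
#' @return Named numeric `c(est_x, est_y, sd)`; the zero sentinel for states
#'   with no memory item (including the wall identity 65).
#' @export
recall <- function(identity, store) {
  if (identity < 1L || identity > 65L) stop("identity out of range 1..65")
  row <- unclass(store)[identity, ]
  c(est_x = unname(row[1]), est_y = unname(row[2]), sd = unname(row[3]))
}

# Vectorised recall used by the observation assembler.
recall_many <- function(identities, store) {
  if (any(identities < 1L | identities > 65L)) stop("identity out of range 1..65")
  unclass(store)[identities, , drop = FALSE]
}
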