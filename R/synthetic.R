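# Synthetic generators with known ground truth for every analysis stage:
# parameterised participants (a planted mix of direction/state responses and
# goal-gradient competence), probe responses under the memory noise model,
# sampling-strategy count matrices, and planted recurrent-unit activation
# patterns for the unit classifier, module identifier and decoders.

#' A synthetic participant's behavioural profile
#'
#' @param p_direction Base probability of answering with the direction
#'   modality when both are available.
#' @param p_state_goal,p_state_landmark,p_state_visited Probability of a
#'   state response when the chosen move's destination is the goal, a
#'   landmark, or a previously visited cell (precedence in that order;
#'   otherwise `1 - p_direction` applies).
#' @param competence Probability of taking the move that most reduces the
#'   estimated distance to the remembered goal (vs a softmax over all valid
#'   moves); 1 = always greedy on the gradient.
#' @param noise A [memory_noise_params()] list driving goal-memory quality.
#' @export
participant_profile <- function(p_direction = 0.75, p_state_goal = 0.8,
                                p_state_landmark = 0.6, p_state_visited = 0.3,
                                competence = 0.9,
                                noise = memory_noise_params()) {
  probs <- c(p_direction, p_state_goal, p_state_landmark, p_state_visited,
             competence)
  stopifnot(all(probs >= 0 & probs <= 1))
  list(p_direction = p_direction, p_state_goal = p_state_goal,
       p_state_landmark = p_state_landmark, p_state_visited = p_state_visited,
       competence = competence, noise = noise)
}

#' Simulate a participant's navigation trajectories
#'
#' Movement follows a noisy gradient toward the remembered (noise-corrupted)
#' goal estimate: with probability `competence` the valid move minimising
#' the estimated remaining distance is taken; otherwise a move is drawn from
#' a softmax over negative estimated distances (temperature grows as
#' competence falls). The response modality is then drawn independently of
#' the chosen move from the profile's destination-contingent probabilities.
#'
#' @param profile A [participant_profile()].
#' @param n_trials Number of trials. @param seed Integer seed.
#' @param task A [task_config()].
#' @return As [evaluate()]: list with `log` and `trials` tibbles.
#' @export
simulate_participant <- function(profile, n_trials, seed = NULL,
                                 task = task_config(env_kinds = "open",
                                                    conditions = "both")) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- expand.grid(condition = task$conditions, kind = task$env_kinds,
                      nl = task$n_landmarks, stringsAsFactors = FALSE)
  logs <- vector("list", n_trials); trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    g <- grid[((i - 1) %% nrow(grid)) + 1, ]
    tk <- task
    tk$conditions <- g$condition; tk$env_kinds <- g$kind
    tk$n_landmarks <- g$nl
    ep <- new_episode(tk, profile$noise)
    run <- .run_participant_trial(profile, ep)
    run$log$trial <- i
    run$log$condition <- g$condition; run$log$env_kind <- g$kind
    run$log$n_landmarks <- g$nl
    logs[[i]] <- run$log
    trials[[i]] <- tibble::tibble(trial = i, condition = g$condition,
                                  env_kind = g$kind, n_landmarks = g$nl,
                                  steps_to_goal = run$steps,
                                  success = run$success, points = run$points)
  }
  list(log = dplyr::bind_rows(logs), trials = dplyr::bind_rows(trials))
}

.run_participant_trial <- function(profile, ep) {
  map <- ep$map; config <- ep$config; st <- ep$state
  goal_est <- recall(map$identity[map$goal[1] + 1L, map$goal[2] + 1L],
                     ep$memory)
  goal_xy <- c(goal_est[["est_x"]], goal_est[["est_y"]])
  lm_set <- paste(map$landmarks[, "row"], map$landmarks[, "col"])
  rows <- list(tibble::tibble(step = 0L, row = st$cell[1], col = st$cell[2],
                              action = NA_integer_, modality = NA_character_,
                              dest_type = NA_character_, visited_before = NA,
                              points = st$points, event = "start"))
  visit_count <- matrix(0L, map$interior_size, map$interior_size)
  visit_count[st$cell[1] + 1L, st$cell[2] + 1L] <- 1L
  repeat {
    mk <- action_mask(st, map)
    valid_dirs <- which(mk[1:4] | mk[5:8])
    # estimated distance of each candidate destination to the remembered
    # goal, plus a per-visit penalty: the remembered goal is noisy, so a
    # pure distance-greedy walker would orbit the (wrong) estimated cell
    # forever; accumulating penalties push the search outward instead
    dists <- vapply(valid_dirs, function(k) {
      dest <- st$cell + .DELTAS[k, ]
      sum(abs(c(dest[2], dest[1]) - goal_xy)) +
        0.75 * visit_count[dest[1] + 1L, dest[2] + 1L]
    }, numeric(1))
    k <- if (stats::runif(1) < profile$competence) {
      valid_dirs[which.min(dists)]
    } else {
      temp <- 1 + 4 * (1 - profile$competence)
      p <- exp(-dists / temp); p <- p / sum(p)
      if (length(valid_dirs) == 1L) valid_dirs else sample(valid_dirs, 1L, prob = p)
    }
    dest <- st$cell + .DELTAS[k, ]
    key <- paste(dest[1], dest[2])
    p_state <- if (all(dest == map$goal)) profile$p_state_goal
      else if (key %in% lm_set) profile$p_state_landmark
      else if (st$visited[dest[1] + 1L, dest[2] + 1L]) profile$p_state_visited
      else 1 - profile$p_direction
    use_state <- stats::runif(1) < p_state
    # honour the modality availability of this step
    if (!st$modalities[["states"]]) use_state <- FALSE
    if (!st$modalities[["directions"]]) use_state <- TRUE
    a <- if (use_state) k + 4L else k
    res <- env_step(st, map, a, config)
    st <- res$state
    visit_count[st$cell[1] + 1L, st$cell[2] + 1L] <-
      visit_count[st$cell[1] + 1L, st$cell[2] + 1L] + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      step = st$step, row = st$cell[1], col = st$cell[2], action = a,
      modality = if (a <= 4L) "direction" else "state",
      dest_type = if (all(st$cell == map$goal)) "goal"
        else if (key %in% lm_set) "landmark" else "non_landmark",
      visited_before = {
        prev <- dplyr::bind_rows(rows)
        any(prev$row == st$cell[1] & prev$col == st$cell[2])
      },
      points = st$points, event = res$event)
    if (st$done) break
  }
  list(log = dplyr::bind_rows(rows), steps = st$step,
       success = !st$truncated, points = st$points)
}

#' Simulate memory-probe responses under the noise model
#'
#' Responses are the true cell plus per-axis Gaussian noise of s.d. `s`,
#' rounded to the nearest cell and clipped to the interior.
#'
#' @param n_probes Number of probes. @param s Noise s.d. (grid units).
#' @param seed Integer seed.
#' @return Tibble `true_row`, `true_col`, `resp_row`, `resp_col`.
#' @export
simulate_probe_responses <- function(n_probes, s, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  true_row <- sample(0:7, n_probes, replace = TRUE)
  true_col <- sample(0:7, n_probes, replace = TRUE)
  clip <- function(x) pmin(7L, pmax(0L, as.integer(round(x))))
  tibble::tibble(true_row = true_row, true_col = true_col,
                 resp_row = clip(true_row + stats::rnorm(n_probes, 0, s)),
                 resp_col = clip(true_col + stats::rnorm(n_probes, 0, s)))
}

#' Simulate landmark-sampling strategies
#'
#' Generates subjects x 64 sampling-count matrices with a named spatial
#' concentration. Each subject spends `16 * blocks` clicks; `"center"`
#' samplers concentrate near the grid centre, `"corner"` samplers near the
#' four corners, `"uniform"` samplers spread evenly, and `"mixture"` splits
#' subjects evenly between centre and corner strategies.
#'
#' @param strategy `"center"`, `"corner"`, `"uniform"` or `"mixture"`.
#' @param n_subjects Number of subjects. @param blocks Trial blocks
#'   aggregated per subject. @param seed Integer seed.
#' @param concentration Softmax sharpness of the spatial preference.
#' @return A subjects x 64 integer matrix in row-major cell order.
#' @export
simulate_sampling_strategies <- function(strategy = c("center", "corner",
                                                      "uniform", "mixture"),
                                         n_subjects, blocks = 4L, seed = NULL,
                                         concentration = 1.5) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cells <- expand.grid(col = 0:7, row = 0:7)[, c("row", "col")]  # row-major
  d_center <- abs(cells$row - 3.5) + abs(cells$col - 3.5)
  corners <- rbind(c(0, 0), c(0, 7), c(7, 0), c(7, 7))
  d_corner <- apply(cells, 1, function(cl)
    min(abs(corners[, 1] - cl[1]) + abs(corners[, 2] - cl[2])))
  weight <- function(strat) switch(strat,
    center = exp(-concentration * d_center),
    corner = exp(-concentration * d_corner),
    uniform = rep(1, 64))
  budget <- 16L * blocks
  draw <- function(strat) {
    w <- weight(strat)
    stats::rmultinom(1, budget, w / sum(w))[, 1]
  }
  strata <- if (strategy == "mixture")
    rep(c("center", "corner"), length.out = n_subjects)
  else rep(strategy, n_subjects)
  out <- t(vapply(strata, draw, numeric(64)))
  rownames(out) <- NULL
  attr(out, "strategy") <- strata
  out
}

#' A planted-unit specification
#'
#' @param type `"spatial"` (quadrant-tuned), `"landmark"`
#'   (adjacency-tuned), `"conjunctive"` (multiplicative quadrant x
#'   landmark), or `"noise"`.
#' @param amplitude Effect amplitude. @param noise_sd Additive noise s.d.
#' @param quadrant Preferred quadrant index 1..4 (spatial/conjunctive).
#' @export
planted_unit_spec <- function(type = c("spatial", "landmark", "conjunctive",
                                       "noise"),
                              amplitude = 1, noise_sd = 0.5, quadrant = 1L) {
  type <- match.arg(type)
  stopifnot(amplitude >= 0)
  list(type = type, amplitude = amplitude, noise_sd = noise_sd,
       quadrant = as.integer(quadrant))
}

#' Generate planted activations over the classification environment suite
#'
#' Composes an [activation_dataset()] whose units carry known response
#' structure: quadrant means, landmark-adjacency bumps, their multiplicative
#' conjunction, or pure noise. Positions are sampled uniformly over the
#' interior per timestep. Optionally wires chosen units linearly into
#' synthetic action logits (ground truth for module identification).
#'
#' @param specs List of [planted_unit_spec()]s (at most 100).
#' @param n_steps Timesteps per environment.
#' @param layouts Landmark layouts (default [classification_layouts()]).
#' @param seed Integer seed.
#' @param wire_direction,wire_state Optional unit indices driving the four
#'   direction / four state logits linearly.
#' @param logit_noise_sd Noise added to wired logits.
#' @export
generate_planted_activations <- function(specs, n_steps = 500L,
                                         layouts = classification_layouts(),
                                         seed = NULL,
                                         wire_direction = NULL,
                                         wire_state = NULL,
                                         logit_noise_sd = 0.05) {
  if (length(specs) > 100L) stop("at most 100 planted units")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_units <- length(specs)
  anns <- list(); acts <- list()
  for (e in seq_along(layouts)) {
    layout <- layouts[[e]]
    row <- sample(0:7, n_steps, replace = TRUE)
    col <- sample(0:7, n_steps, replace = TRUE)
    quadrant <- 1L + (row >= 4) * 2L + (col >= 4)          # 1..4
    near <- vapply(seq_len(n_steps), function(i)
      any(abs(layout[, 1] - row[i]) + abs(layout[, 2] - col[i]) <= 1),
      logical(1))
    A <- matrix(0, n_steps, n_units)
    for (u in seq_len(n_units)) {
      sp <- specs[[u]]
      signal <- switch(sp$type,
        spatial = sp$amplitude * (quadrant == sp$quadrant),
        landmark = sp$amplitude * near,
        conjunctive = sp$amplitude * (quadrant == sp$quadrant) * near,
        noise = 0)
      A[, u] <- signal + stats::rnorm(n_steps, 0, sp$noise_sd)
    }
    acts[[e]] <- A
    anns[[e]] <- tibble::tibble(
      step = seq_len(n_steps), row = row, col = col,
      landmark_adjacent = near,
      goal_adjacent = FALSE, post_landmark = FALSE,
      goal_row = NA_integer_, goal_col = NA_integer_,
      env_id = e, trial = NA_integer_, condition = "both")
  }
  A <- do.call(rbind, acts)
  ann <- dplyr::bind_rows(anns)
  logits <- NULL
  if (!is.null(wire_direction) || !is.null(wire_state)) {
    n <- nrow(A)
    logits <- matrix(stats::rnorm(n * 8, 0, logit_noise_sd), n, 8)
    mix <- function(units, slots) {
      W <- matrix(stats::runif(length(units) * length(slots), 0.5, 1.5),
                  length(units), length(slots))
      logits[, slots] <<- logits[, slots] + A[, units, drop = FALSE] %*% W
    }
    if (!is.null(wire_direction)) mix(wire_direction, 1:4)
    if (!is.null(wire_state)) mix(wire_state, 5:8)
  }
  activation_dataset(A, ann, logits = logits, layouts = layouts)
}
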