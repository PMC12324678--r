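# Model-behaviour evaluation: run trials with greedy (deterministic) action
# selection over masked logits, logging a trajectory record per step and,
# optionally, the LSTM cell-state activations that feed every unit-level
# analysis. A uniform-random-valid-action policy is available as the
# no-learning baseline.

#' Run evaluation trials and log trajectories
#'
#' Conditions, environment kinds and landmark counts are balanced by cycling
#' through their full crossing. Greedy selection takes the argmax of the
#' masked logits (ties broken toward the lowest action index); `"sample"`
#' draws from the masked softmax; `"random"` ignores the network and picks a
#' valid action uniformly (baseline).
#'
#' @param params Network parameters (may be `NULL` for `policy = "random"`).
#' @param n_trials Number of trials.
#' @param task A [task_config()] giving the condition/environment crossing.
#' @param policy `"greedy"`, `"sample"` or `"random"`.
#' @param seed Integer seed.
#' @param lesion Optional unit index set zeroed at every step.
#' @param record_activations If `TRUE`, also return an activation dataset.
#' @param fixed_landmarks Optional n x 2 matrix of fixed landmark cells
#'   (used by the unit-classification environment suite).
#' @param env_id Environment label stored with activations.
#' @param noise Memory [memory_noise_params()].
#' @return A list with `log` (tibble: one row per step plus a step-0 start
#'   row per trial) and `trials` (per-trial summary tibble); when
#'   `record_activations`, also `activations` (steps x 100 cell states),
#'   `logits`, and `annotations`.
#' @export
evaluate <- function(params, n_trials, task = task_config(),
                     policy = c("greedy", "sample", "random"),
                     seed = NULL, lesion = NULL, record_activations = FALSE,
                     fixed_landmarks = NULL, env_id = NA_integer_,
                     noise = memory_noise_params()) {
  policy <- match.arg(policy)
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- expand.grid(condition = task$conditions, kind = task$env_kinds,
                      nl = task$n_landmarks, stringsAsFactors = FALSE)
  logs <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  acts <- if (record_activations) vector("list", n_trials)
  lgts <- if (record_activations) vector("list", n_trials)
  anns <- if (record_activations) vector("list", n_trials)
  obss <- if (record_activations) vector("list", n_trials)

  for (i in seq_len(n_trials)) {
    g <- grid[((i - 1) %% nrow(grid)) + 1, ]
    tk <- task
    tk$conditions <- g$condition; tk$env_kinds <- g$kind
    tk$n_landmarks <- g$nl
    ep <- new_episode(tk, noise, fixed_landmarks = fixed_landmarks,
                      env_id = env_id)
    run <- .run_trial(params, ep, policy, lesion, record_activations)
    run$log$trial <- i
    run$log$condition <- g$condition
    run$log$env_kind <- g$kind
    run$log$n_landmarks <- g$nl
    logs[[i]] <- run$log
    trials[[i]] <- tibble::tibble(
      trial = i, condition = g$condition, env_kind = g$kind,
      n_landmarks = g$nl, steps_to_goal = run$steps,
      success = run$success, points = run$points)
    if (record_activations) {
      acts[[i]] <- run$activations
      lgts[[i]] <- run$logits
      obss[[i]] <- run$observations
      ann <- run$annotations
      ann$trial <- i
      ann$condition <- g$condition
      anns[[i]] <- ann
    }
  }
  out <- list(log = dplyr::bind_rows(logs), trials = dplyr::bind_rows(trials))
  if (record_activations) {
    out$activations <- do.call(rbind, acts)
    out$logits <- do.call(rbind, lgts)
    out$observations <- do.call(rbind, obss)
    out$annotations <- dplyr::bind_rows(anns)
  }
  out
}

.run_trial <- function(params, ep, policy, lesion, record) {
  map <- ep$map; config <- ep$config; memory <- ep$memory
  st <- ep$state
  state <- if (!is.null(params)) initial_state(params, 1L)
  max_rows <- config$max_steps + 1L
  step_v <- integer(max_rows); r_v <- integer(max_rows); c_v <- integer(max_rows)
  act_v <- integer(max_rows); mod_v <- character(max_rows)
  dest_v <- character(max_rows); vis_v <- logical(max_rows)
  pts_v <- numeric(max_rows); ev_v <- character(max_rows)
  lm_set <- paste(map$landmarks[, "row"], map$landmarks[, "col"])
  step_v[1] <- 0L; r_v[1] <- st$cell[1]; c_v[1] <- st$cell[2]
  act_v[1] <- NA_integer_; mod_v[1] <- NA_character_
  dest_v[1] <- NA_character_; vis_v[1] <- NA
  pts_v[1] <- st$points; ev_v[1] <- "start"
  n <- 1L
  if (record) {
    A <- matrix(0, max_rows, attr(params, "config")$n_recurrent)
    L <- matrix(0, max_rows, 8)
    OBS <- matrix(0, max_rows, attr(params, "config")$n_input)
    ann_r <- integer(max_rows); ann_c <- integer(max_rows)
    ann_lm <- logical(max_rows); ann_goal <- logical(max_rows)
    ann_post <- logical(max_rows); ann_step <- integer(max_rows)
    nrec <- 0L
    seen_landmark <- FALSE
  }
  obs_base <- .obs_base(map, config)
  repeat {
    obs <- .obs_fill(obs_base, st, map, memory)
    mk <- action_mask(st, map)
    if (policy == "random") {
      valid <- which(mk)
      a <- if (length(valid) == 1L) valid else sample(valid, 1L)
    } else {
      fwd <- forward(params, obs, state, lesion = lesion)
      state <- fwd$state
      ml <- mask_logits(fwd$logits[1, ], mk)
      a <- if (policy == "greedy") which.max(ml) else {
        p <- exp(ml - max(ml)); sample.int(8L, 1L, prob = p)
      }
      if (record) {
        nrec <- nrec + 1L
        A[nrec, ] <- state$c[1, ]
        L[nrec, ] <- fwd$logits[1, ]
        OBS[nrec, ] <- obs
        ann_step[nrec] <- st$step + 1L
        ann_r[nrec] <- st$cell[1]; ann_c[nrec] <- st$cell[2]
        here_lm <- .near_landmark(st$cell, map)
        if (paste(st$cell[1], st$cell[2]) %in% lm_set) seen_landmark <- TRUE
        ann_lm[nrec] <- here_lm
        ann_goal[nrec] <- sum(abs(st$cell - map$goal)) <= 1
        ann_post[nrec] <- seen_landmark
      }
    }
    res <- env_step(st, map, a, config)
    st <- res$state
    n <- n + 1L
    step_v[n] <- st$step; r_v[n] <- st$cell[1]; c_v[n] <- st$cell[2]
    act_v[n] <- a
    mod_v[n] <- if (a <= 4L) "direction" else "state"
    key <- paste(st$cell[1], st$cell[2])
    dest_v[n] <- if (all(st$cell == map$goal)) "goal"
      else if (key %in% lm_set) "landmark" else "non_landmark"
    # visited_before refers to occupancy prior to this move
    vis_v[n] <- any(r_v[1:(n - 1)] == st$cell[1] & c_v[1:(n - 1)] == st$cell[2])
    pts_v[n] <- st$points; ev_v[n] <- res$event
    if (st$done) break
  }
  log <- tibble::tibble(step = step_v[1:n], row = r_v[1:n], col = c_v[1:n],
                        action = act_v[1:n], modality = mod_v[1:n],
                        dest_type = dest_v[1:n], visited_before = vis_v[1:n],
                        points = pts_v[1:n], event = ev_v[1:n])
  out <- list(log = log, steps = st$step, success = !st$truncated,
              points = st$points)
  if (record) {
    out$activations <- A[seq_len(nrec), , drop = FALSE]
    out$logits <- L[seq_len(nrec), , drop = FALSE]
    out$observations <- OBS[seq_len(nrec), , drop = FALSE]
    out$annotations <- tibble::tibble(
      step = ann_step[seq_len(nrec)], row = ann_r[seq_len(nrec)],
      col = ann_c[seq_len(nrec)], landmark_adjacent = ann_lm[seq_len(nrec)],
      goal_adjacent = ann_goal[seq_len(nrec)],
      post_landmark = ann_post[seq_len(nrec)],
      goal_row = map$goal[1], goal_col = map$goal[2],
      env_id = ep$env_id)
  }
  out
}

# On or 4-adjacent to a landmark (diagonals excluded).
.near_landmark <- function(cell, map) {
  lms <- map$landmarks
  any(abs(lms[, "row"] - cell[1]) + abs(lms[, "col"] - cell[2]) <= 1)
}
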