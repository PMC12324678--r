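# Masked proximal policy optimization for the recurrent agent: clipped
# surrogate policy loss, squared-error value loss, and an entropy bonus
# computed over valid (unmasked) actions only,
#   L = L_policy + c1 * L_value - c2 * L_entropy,
# minimized with Adam under global-norm gradient clipping. Advantages use
# generalized advantage estimation (gamma = 0.99, lambda = 0.95 defaults;
# neither appears in the printed hyperparameter table, so the reference
# recurrent-PPO defaults are adopted and both stay configurable).

#' PPO training configuration
#'
#' Defaults follow the printed hyperparameters (learning rate 3e-4, value
#' coefficient 0.5, entropy coefficient 0.001, clip range 0.2, gradient-clip
#' max norm 0.5). `scale = "full"` reproduces the study-scale geometry (128
#' parallel environments x 8,192 steps per update x 8,000 updates, i.e.,
#' 1,048,576 environment steps per update); `scale = "desk"` is the
#' workstation-sized default used throughout the package's own runs.
#'
#' @param scale `"desk"` or `"full"`.
#' @export
ppo_config <- function(learning_rate = 3e-4, c1 = 0.5, c2 = 0.001,
                       clip_range = 0.2, max_grad_norm = 0.5,
                       gamma = 0.99, gae_lambda = 0.95,
                       n_envs = 8L, n_steps = 256L, n_updates = 300L,
                       n_epochs = 4L,
                       reward_step = -0.05, reward_goal = 1.0,
                       scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") { n_envs <- 128L; n_steps <- 8192L; n_updates <- 8000L }
  stopifnot(clip_range > 0, clip_range < 1, c1 >= 0, c2 >= 0)
  list(learning_rate = learning_rate, c1 = c1, c2 = c2,
       clip_range = clip_range, max_grad_norm = max_grad_norm,
       gamma = gamma, gae_lambda = gae_lambda,
       n_envs = as.integer(n_envs), n_steps = as.integer(n_steps),
       n_updates = as.integer(n_updates), n_epochs = as.integer(n_epochs),
       reward_step = reward_step, reward_goal = reward_goal, scale = scale)
}

#' Task-distribution configuration for training and evaluation
#'
#' Which environment kinds, action conditions and unique-landmark counts are
#' interleaved (each episode samples one combination uniformly), and the
#' condition-specific probability that the direction modality is available
#' under random alternation (0.75 open field, 0.50 cluttered).
#' @export
task_config <- function(env_kinds = c("open", "cluttered"),
                        conditions = c("both", "directions_only",
                                       "states_only", "random_alternation"),
                        n_landmarks = c(2L, 4L, 8L, 16L),
                        p_direction = c(open = 0.75, cluttered = 0.5),
                        placement_variant = "strict", max_steps = 200L) {
  list(env_kinds = env_kinds, conditions = conditions,
       n_landmarks = as.integer(n_landmarks), p_direction = p_direction,
       placement_variant = placement_variant, max_steps = as.integer(max_steps))
}

# Sample one episode's task bundle (map, start, memory, episode config).
new_episode <- function(task, noise = memory_noise_params(),
                        fixed_landmarks = NULL, env_id = NA_integer_) {
  kind <- if (length(task$env_kinds) > 1)
    sample(task$env_kinds, 1) else task$env_kinds
  condition <- if (length(task$conditions) > 1)
    sample(task$conditions, 1) else task$conditions
  nl <- if (length(task$n_landmarks) > 1)
    sample(task$n_landmarks, 1) else task$n_landmarks
  if (is.null(fixed_landmarks)) {
    trial <- generate_trial(NULL, kind, nl, task$placement_variant)
  } else {
    trial <- generate_trial_fixed(fixed_landmarks, kind)
  }
  mc <- draw_landmark_noise_params(noise)
  memory <- build_memory_store(trial$map, mc, noise)
  config <- episode_config(condition,
                           p_direction_available = task$p_direction[[kind]],
                           max_steps = task$max_steps)
  list(map = trial$map, start = trial$start, config = config,
       memory = memory, env_id = env_id,
       obs_base = .obs_base(trial$map, config),
       state = env_reset(trial$map, trial$start, config))
}

# Trial with landmark cells fixed at given (row, col) positions, splitting
# the 16-exposure budget equally (used by the unit-classification suite).
generate_trial_fixed <- function(landmark_cells, kind = "open",
                                 max_attempts = 100L) {
  lms <- cbind(landmark_cells,
               n_exposures = as.integer(16L / nrow(landmark_cells)))
  colnames(lms) <- c("row", "col", "n_exposures")
  for (i in seq_len(max_attempts)) {
    map <- generate_map(NULL, kind, nrow(lms), "strict")
    map$landmarks <- lms
    # re-draw the goal so it avoids the fixed landmarks
    elig <- .eligible_cells(map$obstacle_grid, edge_ok = FALSE)
    keep <- !(paste(elig[, 1], elig[, 2]) %in% paste(lms[, 1], lms[, 2]))
    elig <- elig[keep, , drop = FALSE]
    map$goal <- as.integer(elig[sample.int(nrow(elig), 1L), ])
    start <- tryCatch(choose_start(map), metanav_no_start = function(e) NULL)
    if (!is.null(start)) return(list(map = map, start = start))
  }
  stop("no feasible fixed-landmark trial after ", max_attempts, " attempts")
}

#' Generalized advantage estimation
#'
#' @param rewards,values T x B matrices (time by environment).
#' @param dones T x B logical; `TRUE` where the episode ended at step t
#'   (truncation bootstraps are folded into the reward upstream).
#' @param last_values Length-B values of the state after step T, used to
#'   bootstrap unfinished episodes.
#' @param gamma,lambda Discount and GAE mixing parameters.
#' @return List of T x B matrices `advantages` and `returns`
#'   (returns = advantages + values).
#' @export
compute_advantages <- function(rewards, values, dones, last_values,
                               gamma = 0.99, lambda = 0.95) {
  Tn <- nrow(rewards); B <- ncol(rewards)
  adv <- matrix(0, Tn, B)
  gae <- numeric(B)
  for (t in Tn:1) {
    v_next <- if (t == Tn) last_values else values[t + 1, ]
    not_done <- 1 - dones[t, ]
    delta <- rewards[t, ] + gamma * v_next * not_done - values[t, ]
    gae <- delta + gamma * lambda * not_done * gae
    adv[t, ] <- gae
  }
  list(advantages = adv, returns = adv + values)
}

# Masked softmax probabilities and per-row log-probabilities.
masked_policy <- function(logits, masks) {
  ml <- mask_logits(logits, masks)
  lp <- log_softmax(ml)
  list(lp = lp, p = exp(lp) * masks)
}

#' PPO losses for a rollout batch
#'
#' Recomputes the network forward pass over the batch and returns the
#' clipped-surrogate policy loss, the squared-error value loss, the entropy
#' of the masked policy (over valid actions only), and the total
#' `policy + c1 * value - c2 * entropy`. The sign convention makes
#' minimizing the total equivalent to maximizing the clipped surrogate
#' objective plus the entropy bonus.
#'
#' @param params Network parameters.
#' @param batch Rollout batch: `xs` (list of T observation matrices, B x 48),
#'   `resets` (T x B logical), `actions`, `old_logp`, `advantages`,
#'   `returns` (T x B matrices) and `masks` (list of T logical B x 8
#'   matrices).
#' @param config A [ppo_config()].
#' @return List `policy`, `value`, `entropy`, `total` (all scalars).
#' @export
ppo_losses <- function(params, batch, config = ppo_config()) {
  .ppo_losses_grads(params, batch, config, want_grads = FALSE)$losses
}

.ppo_losses_grads <- function(params, batch, config, want_grads = TRUE) {
  Tn <- length(batch$xs); B <- nrow(batch$xs[[1]])
  N <- Tn * B
  fw <- seq_forward(params, batch$xs, batch$resets)
  logits <- fw$heads$logits
  value <- fw$heads$value
  masks <- do.call(rbind, batch$masks)      # N x 8, row (t-1)*B + b
  pol <- masked_policy(logits, masks)
  # flatten T x B quantities to match the stacked row order (t-1)*B + b
  act <- integer(N)
  for (t in seq_len(Tn)) act[((t - 1) * B + 1):(t * B)] <- batch$actions[t, ]
  old_lp <- numeric(N); A <- numeric(N); R <- numeric(N)
  for (t in seq_len(Tn)) {
    idx <- ((t - 1) * B + 1):(t * B)
    old_lp[idx] <- batch$old_logp[t, ]
    A[idx] <- batch$advantages[t, ]
    R[idx] <- batch$returns[t, ]
  }
  sel <- cbind(seq_len(N), act)
  new_lp <- pol$lp[sel]
  ratio <- exp(new_lp - old_lp)
  eps <- config$clip_range
  surr1 <- ratio * A
  surr2 <- pmin(pmax(ratio, 1 - eps), 1 + eps) * A
  l_policy <- -mean(pmin(surr1, surr2))
  l_value <- mean((value - R)^2)
  plp <- pol$p * pol$lp
  plp[!masks] <- 0
  ent <- -rowSums(plp)
  l_entropy <- mean(ent)
  l_total <- l_policy + config$c1 * l_value - config$c2 * l_entropy
  losses <- list(policy = l_policy, value = l_value, entropy = l_entropy,
                 total = l_total)
  if (!want_grads) return(list(losses = losses))

  # Gradient of the total loss w.r.t. logits and value outputs.
  active <- as.numeric(surr1 <= surr2)      # unclipped branch carries gradient
  dlp_chosen <- -(A * ratio * active) / N
  dlogits <- -pol$p * dlp_chosen            # -p_j * dlp for all j ...
  dlogits[sel] <- dlogits[sel] + dlp_chosen # ... + dlp on the chosen slot
  # entropy: d(-c2 * mean(H))/dlogit_j = c2/N * p_j * (lp_j + H)
  dent <- pol$p * (pol$lp + ent)
  dent[!masks] <- 0
  dlogits <- dlogits + (config$c2 / N) * dent
  dvalue <- config$c1 * 2 * (value - R) / N
  grads <- seq_backward(params, fw, dlogits, dvalue)
  list(losses = losses, grads = grads)
}

# Collect one on-policy rollout from B freshly started environments.
collect_rollout <- function(params, config, task,
                            noise = memory_noise_params()) {
  B <- config$n_envs; Tn <- config$n_steps
  envs <- lapply(seq_len(B), function(b) new_episode(task, noise))
  state <- initial_state(params, B)
  xs <- vector("list", Tn)
  masks <- vector("list", Tn)
  resets <- matrix(FALSE, Tn, B); resets[1, ] <- TRUE
  actions <- matrix(0L, Tn, B); old_logp <- matrix(0, Tn, B)
  rewards <- matrix(0, Tn, B); dones <- matrix(FALSE, Tn, B)
  values <- matrix(0, Tn, B)
  ep_lengths <- integer(0); ep_rewards <- numeric(0)
  need_reset <- rep(FALSE, B)

  for (t in seq_len(Tn)) {
    for (b in which(need_reset)) {
      envs[[b]] <- new_episode(task, noise)
      resets[t, b] <- TRUE
      need_reset[b] <- FALSE
    }
    if (any(resets[t, ])) {
      state$h[resets[t, ], ] <- 0; state$c[resets[t, ], ] <- 0
    }
    X <- do.call(rbind, lapply(envs, function(e)
      .obs_fill(e$obs_base, e$state, e$map, e$memory)))
    xs[[t]] <- X
    st <- lstm_step(params, X, state$h, state$c)
    state <- list(h = st$h, c = st$c)
    hd <- heads_forward(params, st$h)
    mk <- t(vapply(envs, function(e) action_mask(e$state, e$map), logical(8)))
    masks[[t]] <- mk
    pol <- masked_policy(hd$logits, mk)
    values[t, ] <- hd$value
    for (b in seq_len(B)) {
      a <- sample.int(8L, 1L, prob = pol$p[b, ])
      actions[t, b] <- a
      old_logp[t, b] <- pol$lp[b, a]
      res <- env_step(envs[[b]]$state, envs[[b]]$map, a, envs[[b]]$config,
                      mask = mk[b, ])
      envs[[b]]$state <- res$state
      r <- config$reward_step
      if (res$event == "goal") r <- r + config$reward_goal
      if (res$state$done) {
        ep_lengths <- c(ep_lengths, res$state$step)
        ep_rewards <- c(ep_rewards,
                        config$reward_step * res$state$step +
                          if (res$event == "goal") config$reward_goal else 0)
        if (res$event == "truncated") {
          # non-terminal truncation: bootstrap the cut-off return
          obs_n <- .obs_fill(envs[[b]]$obs_base, res$state, envs[[b]]$map,
                             envs[[b]]$memory)
          v_n <- forward(params, obs_n,
                         list(h = state$h[b, , drop = FALSE],
                              c = state$c[b, , drop = FALSE]))$value
          r <- r + config$gamma * v_n
        }
        dones[t, b] <- TRUE
        need_reset[b] <- TRUE
      }
      rewards[t, b] <- r
    }
  }
  # bootstrap values for episodes still running at rollout end
  last_values <- numeric(B)
  alive <- !need_reset
  if (any(alive)) {
    Xl <- do.call(rbind, lapply(envs[alive], function(e)
      .obs_fill(e$obs_base, e$state, e$map, e$memory)))
    stl <- lstm_step(params, Xl, state$h[alive, , drop = FALSE],
                     state$c[alive, , drop = FALSE])
    last_values[alive] <- heads_forward(params, stl$h)$value
  }
  list(xs = xs, masks = masks, resets = resets, actions = actions,
       old_logp = old_logp, rewards = rewards, dones = dones,
       values = values, last_values = last_values,
       ep_lengths = ep_lengths, ep_rewards = ep_rewards)
}

#' Train the recurrent agent with masked PPO
#'
#' Interleaves the configured environment kinds, action conditions and
#' landmark counts across episodes; every update collects a fresh on-policy
#' rollout, estimates advantages with GAE, and takes `n_epochs` full-batch
#' Adam steps on the clipped objective under global-norm gradient clipping.
#'
#' @param task A [task_config()]. @param net A [network_config()].
#' @param config A [ppo_config()]. @param seed Integer seed (all randomness
#'   in training flows through it).
#' @param verbose Print a progress line every `verbose` updates (0 = quiet).
#' @return List `params` (trained network) and `curve`, a tibble with one
#'   row per update: mean episode length and reward among episodes finished
#'   in that rollout, the three loss components, and the clipped gradient
#'   norm.
#' @export
train <- function(task = task_config(), net = network_config(),
                  config = ppo_config(), seed = 1L,
                  noise = memory_noise_params(), verbose = 0L) {
  set.seed(as.integer(seed))
  params <- init_network(net)
  opt <- adam_init(params)
  curve <- vector("list", config$n_updates)
  for (upd in seq_len(config$n_updates)) {
    ro <- collect_rollout(params, config, task, noise)
    ga <- compute_advantages(ro$rewards, ro$values, ro$dones, ro$last_values,
                             config$gamma, config$gae_lambda)
    adv <- ga$advantages
    adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
    batch <- list(xs = ro$xs, resets = ro$resets, actions = ro$actions,
                  old_logp = ro$old_logp, advantages = adv,
                  returns = ga$returns, masks = ro$masks)
    losses <- NULL; gnorm <- NA_real_
    for (ep in seq_len(config$n_epochs)) {
      lg <- .ppo_losses_grads(params, batch, config)
      if (!is.finite(lg$losses$total))
        stop("training diverged at update ", upd, ": non-finite loss ",
             format(lg$losses$total))
      grads <- clip_gradients(lg$grads, config$max_grad_norm)
      gnorm <- attr(grads, "global_norm")
      stepr <- adam_step(params, grads, opt, lr = config$learning_rate)
      params <- stepr$params; opt <- stepr$opt
      if (is.null(losses)) losses <- lg$losses
    }
    curve[[upd]] <- tibble::tibble(
      update = upd,
      mean_ep_length = if (length(ro$ep_lengths)) mean(ro$ep_lengths) else NA,
      mean_ep_reward = if (length(ro$ep_rewards)) mean(ro$ep_rewards) else NA,
      n_episodes = length(ro$ep_lengths),
      loss_policy = losses$policy, loss_value = losses$value,
      loss_entropy = losses$entropy, grad_norm = gnorm)
    if (verbose > 0 && upd %% verbose == 0)
      message(sprintf("update %d/%d  ep_len %.1f  reward %.2f",
                      upd, config$n_updates, curve[[upd]]$mean_ep_length,
                      curve[[upd]]$mean_ep_reward))
  }
  list(params = params, curve = dplyr::bind_rows(curve))
}
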