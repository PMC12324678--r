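# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the BFS oracle builds a lattice graph, and the
# PPO loss oracle recomputes every quantity with scalar loops from
# per-step forward() calls.

# Shortest-path oracle on the 8x8 interior via igraph.
bfs_oracle <- function(map, a, b) {
  n <- map$interior_size
  cells <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  id <- function(r, c) r * n + c + 1
  edges <- c()
  for (i in seq_len(nrow(cells))) {
    r <- cells$row[i]; c <- cells$col[i]
    if (map$obstacle_grid[r + 1, c + 1]) next
    for (d in list(c(0, 1), c(1, 0))) {
      nr <- r + d[1]; nc <- c + d[2]
      if (nr < n && nc < n && !map$obstacle_grid[nr + 1, nc + 1])
        edges <- c(edges, id(r, c), id(nr, nc))
    }
  }
  g <- igraph::make_empty_graph(n * n, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  d <- igraph::distances(g, v = id(a[1], a[2]), to = id(b[1], b[2]))
  as.numeric(d)
}

# Scalar-loop PPO loss oracle. Uses single-step forward() calls (a separate
# code path from seq_forward) and plain loops for every reduction.
ppo_loss_oracle <- function(params, batch, config) {
  Tn <- length(batch$xs); B <- nrow(batch$xs[[1]])
  nr <- attr(params, "config")$n_recurrent
  l_pol_terms <- c(); l_val_terms <- c(); l_ent_terms <- c()
  for (b in seq_len(B)) {
    state <- list(h = matrix(0, 1, nr), c = matrix(0, 1, nr))
    for (t in seq_len(Tn)) {
      if (batch$resets[t, b]) state <- list(h = matrix(0, 1, nr),
                                            c = matrix(0, 1, nr))
      fw <- forward(params, batch$xs[[t]][b, ], state)
      state <- fw$state
      mask <- batch$masks[[t]][b, ]
      z <- fw$logits[1, ]
      z[!mask] <- -1e8
      zmax <- max(z)
      probs <- exp(z - zmax) / sum(exp(z - zmax))
      a <- batch$actions[t, b]
      lp_a <- log(probs[a])
      ratio <- exp(lp_a - batch$old_logp[t, b])
      A <- batch$advantages[t, b]
      clipped <- min(max(ratio, 1 - config$clip_range), 1 + config$clip_range)
      l_pol_terms <- c(l_pol_terms, min(ratio * A, clipped * A))
      l_val_terms <- c(l_val_terms, (fw$value - batch$returns[t, b])^2)
      ent <- 0
      for (j in which(mask)) if (probs[j] > 0)
        ent <- ent - probs[j] * log(probs[j])
      l_ent_terms <- c(l_ent_terms, ent)
    }
  }
  l_policy <- -mean(l_pol_terms)
  l_value <- mean(l_val_terms)
  l_entropy <- mean(l_ent_terms)
  list(policy = l_policy, value = l_value, entropy = l_entropy,
       total = l_policy + config$c1 * l_value - config$c2 * l_entropy)
}

# Random rollout batch through the real environment (masked), for loss
# oracle comparisons.
random_batch <- function(params, Tn = 8, B = 2,
                         task = task_config(env_kinds = "open",
                                            conditions = "both")) {
  cfg <- ppo_config(n_envs = B, n_steps = Tn)
  ro <- metanav:::collect_rollout(params, cfg, task)
  ga <- compute_advantages(ro$rewards, ro$values, ro$dones, ro$last_values,
                           cfg$gamma, cfg$gae_lambda)
  list(xs = ro$xs, resets = ro$resets, actions = ro$actions,
       old_logp = ro$old_logp, advantages = ga$advantages,
       returns = ga$returns, masks = ro$masks)
}

# Brute-force 2-D Gaussian smoothing oracle with half-sample symmetric
# padding, written as direct nested loops over the padded matrix.
smooth_oracle <- function(mat, sigma) {
  r <- max(1, ceiling(3 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  n <- nrow(mat); m <- ncol(mat)
  ridx <- c(r:1, 1:n, n:(n - r + 1))
  pad <- mat[ridx, ][, c(r:1, 1:m, m:(m - r + 1))]
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m)
    out[i, j] <- sum(pad[i:(i + 2 * r), j:(j + 2 * r)] * K)
  out
}
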