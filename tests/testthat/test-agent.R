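test_that("network initialization has the stated shapes and is seeded", {
  p1 <- init_network(seed = 1)
  p2 <- init_network(seed = 1)
  expect_identical(p1, p2)
  expect_equal(dim(p1$Wx), c(48L, 400L))
  expect_equal(dim(p1$Wh), c(100L, 400L))
  f <- forward(p1, rep(0, 48))
  expect_length(f$logits, 8L)
  expect_length(f$value, 1L)
  expect_true(all(is.finite(c(f$logits, f$value))))
})

test_that("forward is pure, resets cleanly, and stays finite", {
  p <- init_network(seed = 2)
  withr::with_seed(3, obs <- matrix(rnorm(20 * 48), 20, 48))
  st <- initial_state(p)
  f1 <- forward(p, obs[1, ], st)
  f2 <- forward(p, obs[1, ], st)
  expect_identical(f1, f2)
  expect_error(forward(p, rep(0, 47)), "48")

  # first-step outputs after a reset are independent of any prior episode
  st_run <- initial_state(p)
  for (i in 1:10) st_run <- forward(p, obs[i, ], st_run)$state
  fresh <- forward(p, obs[11, ], initial_state(p))
  again <- forward(p, obs[11, ], initial_state(p))
  expect_identical(fresh$logits, again$logits)

  withr::with_seed(4, big <- matrix(rnorm(500 * 48, sd = 3), 500, 48))
  st <- initial_state(p)
  for (i in 1:500) {
    f <- forward(p, big[i, ], st)
    st <- f$state
    expect_true(all(is.finite(c(f$logits, f$value))))
  }
})

test_that("logit masking suppresses invalid actions without touching valid ones", {
  logits <- c(1, 2, 3, 0.5, -1, 0, 2.5, 1.5)
  expect_identical(mask_logits(logits, rep(TRUE, 8)), logits)
  mask <- rep(TRUE, 8); mask[3] <- FALSE
  ml <- mask_logits(logits, mask)
  expect_identical(ml[-3], logits[-3])
  p <- exp(ml - max(ml)); p <- p / sum(p)
  expect_lt(p[3], 1e-30)
  expect_true(mask[which.max(ml)])
  expect_error(mask_logits(logits, rep(FALSE, 8)), "masked")
})

test_that("PPO losses match hand-derived values in analytic cases", {
  p <- init_network(seed = 5)
  cfg <- ppo_config()
  withr::with_seed(6, batch <- random_batch(p, Tn = 4, B = 2))

  # new policy = old policy and zero advantage: exactly zero policy loss
  b0 <- batch
  b0$advantages <- b0$advantages * 0
  expect_equal(ppo_losses(p, b0, cfg)$policy, 0)

  # single sample with ratio 1.5 and advantage 1: min(1.5, 1.2) -> -1.2
  one <- list(xs = list(batch$xs[[1]][1, , drop = FALSE]),
              resets = matrix(TRUE, 1, 1),
              masks = list(batch$masks[[1]][1, , drop = FALSE]),
              actions = matrix(batch$actions[1, 1], 1, 1),
              old_logp = matrix(0, 1, 1),
              advantages = matrix(1, 1, 1),
              returns = matrix(0, 1, 1))
  # choose old_logp so the ratio is exactly 1.5
  fw <- forward(p, one$xs[[1]][1, ])
  ml <- mask_logits(fw$logits[1, ], one$masks[[1]][1, ])
  lp <- ml - log(sum(exp(ml - max(ml)))) - max(ml)
  one$old_logp[1, 1] <- lp[one$actions[1, 1]] - log(1.5)
  expect_equal(ppo_losses(p, one, cfg)$policy, -1.2, tolerance = 1e-10)

  # clipping plateau: pushing the ratio further beyond 1 + eps with A > 0
  # leaves the policy loss unchanged
  l_a <- ppo_losses(p, one, cfg)$policy
  one$old_logp[1, 1] <- lp[one$actions[1, 1]] - log(3)
  l_b <- ppo_losses(p, one, cfg)$policy
  expect_equal(l_a, l_b)
})

test_that("PPO losses agree with an independent scalar-loop oracle", {
  p <- init_network(seed = 7)
  cfg <- ppo_config()
  withr::with_seed(8, {
    for (i in 1:10) {
      batch <- random_batch(p, Tn = 6, B = 2)
      got <- ppo_losses(p, batch, cfg)
      want <- ppo_loss_oracle(p, batch, cfg)
      for (nm in names(want))
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-6)
    }
  })
})

test_that("advantage estimation satisfies its closed-form cases", {
  z <- matrix(0, 5, 2)
  out <- compute_advantages(z, z, z > 1, c(0, 0))
  expect_equal(out$advantages, z)
  expect_equal(out$returns, z)

  # single terminal reward 1, gamma = lambda = 1, V = 0: every A_t = 1
  r <- matrix(0, 4, 1); r[4, 1] <- 1
  d <- matrix(FALSE, 4, 1); d[4, 1] <- TRUE
  out <- compute_advantages(r, r * 0, d, 0, gamma = 1, lambda = 1)
  expect_equal(out$advantages, matrix(1, 4, 1))

  # lambda = 1: A_t + V_t telescopes to the discounted Monte-Carlo return
  withr::with_seed(9, {
    r <- matrix(rnorm(6), 6, 1); v <- matrix(rnorm(6), 6, 1)
    d <- matrix(FALSE, 6, 1); d[6, 1] <- TRUE
    gamma <- 0.9
    out <- compute_advantages(r, v, d, 0, gamma = gamma, lambda = 1)
    mc <- rev(cumsum(rev(r[, 1] * gamma^(0:5)))) / gamma^(0:5)
    expect_equal(out$returns[, 1], mc)
  })
})

test_that("gradient clipping bounds the global norm", {
  withr::with_seed(10, grads <- list(a = matrix(rnorm(20, sd = 5), 4, 5),
                                     b = rnorm(7, sd = 5)))
  clipped <- clip_gradients(grads, 0.5)
  norm <- sqrt(sum(vapply(clipped, function(g) sum(g^2), numeric(1))))
  expect_lte(norm, 0.5 + 1e-6)
  small <- list(a = matrix(0.001, 2, 2))
  expect_identical(clip_gradients(small, 0.5)$a, small$a)
})

test_that("zero updates return the initial parameters unchanged", {
  task <- task_config(env_kinds = "open", conditions = "both")
  res <- train(task, network_config(), ppo_config(n_updates = 0L), seed = 11)
  set.seed(11)
  expect_identical(res$params, init_network(network_config()))
  expect_equal(nrow(res$curve), 0L)
})

test_that("a short training run stays finite and respects the gradient cap", {
  task <- task_config(env_kinds = "open", conditions = "both",
                      n_landmarks = 4L)
  cfg <- ppo_config(n_envs = 2L, n_steps = 32L, n_updates = 3L, n_epochs = 2L)
  res <- train(task, network_config(), cfg, seed = 12)
  expect_equal(nrow(res$curve), 3L)
  expect_true(all(is.finite(res$curve$loss_policy)))
  expect_true(all(res$curve$grad_norm <= 0.5 + 1e-6))
})

test_that("greedy evaluation takes only valid actions and logs consistent trials", {
  p <- init_network(seed = 13)
  task <- task_config(env_kinds = c("open", "cluttered"),
                      conditions = c("both", "random_alternation"))
  ev <- evaluate(p, 12, task, policy = "greedy", seed = 14)
  expect_true(all(ev$log$row >= 0 & ev$log$row <= 7))
  expect_true(all(ev$log$col >= 0 & ev$log$col <= 7))
  expect_true(all(ev$trials$steps_to_goal <= 200))
  # every step moves to a 4-neighbour
  for (tr in split(ev$log, ev$log$trial)) {
    d <- abs(diff(tr$row)) + abs(diff(tr$col))
    expect_true(all(d == 1))
  }
  # trial summaries agree with the step log
  per_trial <- tapply(ev$log$step, ev$log$trial, max)
  expect_equal(as.vector(per_trial), ev$trials$steps_to_goal)
})

test_that("recorded activations replay exactly from logged observations", {
  p <- init_network(seed = 15)
  ev <- evaluate(p, 2, task_config(env_kinds = "open", conditions = "both"),
                 policy = "greedy", seed = 16, record_activations = TRUE)
  ann <- ev$annotations
  for (tr in unique(ann$trial)) {
    rows <- which(ann$trial == tr)
    st <- initial_state(p)
    for (i in rows) {
      f <- forward(p, ev$observations[i, ], st)
      st <- f$state
      expect_equal(unname(st$c[1, ]), unname(ev$activations[i, ]),
                   tolerance = 1e-12)
      expect_equal(unname(f$logits[1, ]), unname(ev$logits[i, ]),
                   tolerance = 1e-12)
    }
  }
})
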