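test_that("Gaussian smoothing preserves mass and matches a brute-force oracle", {
  withr::with_seed(1, m <- matrix(rnorm(64), 8, 8))
  sm <- metanav:::gaussian_smooth(m, 0.7)
  expect_equal(mean(sm), mean(m), tolerance = 1e-6)   # reflective boundary
  expect_equal(sm, smooth_oracle(m, 0.7), tolerance = 1e-12)

  flat <- matrix(3, 8, 8)
  expect_equal(metanav:::gaussian_smooth(flat, 0.7), flat)

  imp <- matrix(0, 8, 8); imp[4, 5] <- 1
  smi <- metanav:::gaussian_smooth(imp, 0.7)
  expect_equal(which(smi == max(smi)), which(imp == 1))
  expect_true(smi[4, 4] > smi[4, 3])                  # mass decays outward
})

test_that("spatial maps average activations per cell and impute unvisited cells", {
  withr::with_seed(2, {
    ds <- generate_planted_activations(list(planted_unit_spec("spatial",
      amplitude = 2, noise_sd = 0.01, quadrant = 1)), n_steps = 800)
  })
  maps <- unit_spatial_maps(ds, 1, sigma = 0)
  expect_length(maps, 4L)
  # quadrant 1 (rows 0-3, cols 0-3) carries the planted amplitude
  expect_gt(mean(maps[[1]][1:4, 1:4]), 1.5)
  expect_lt(mean(maps[[1]][5:8, 5:8]), 0.5)
})

test_that("the unit classifier recovers planted response types", {
  withr::with_seed(3, {
    specs <- c(
      lapply(1:4, function(q) planted_unit_spec("spatial", 1, 0.5, q)),
      lapply(1:4, function(q) planted_unit_spec("landmark", 1, 0.5)),
      lapply(1:4, function(q) planted_unit_spec("conjunctive", 2, 0.5, q)))
    ds <- generate_planted_activations(specs, n_steps = 1500)
    cls <- classify_units(ds)
  })
  expect_equal(cls$label[1:4], rep("spatial", 4))
  expect_equal(cls$label[5:8], rep("landmark", 4))
  expect_equal(cls$label[9:12], rep("conjunctive", 4))
})

test_that("pure-noise units are mostly labelled none without smoothing", {
  withr::with_seed(4, {
    specs <- replicate(40, planted_unit_spec("noise", 0, 1), simplify = FALSE)
    ds <- generate_planted_activations(specs, n_steps = 600)
    cls <- classify_units(ds, sigma = 0)
  })
  # three independent tests at alpha = .05: P(all null) ~ .95^3 ~ 0.857
  expect_gt(mean(cls$label == "none"), 0.7)
  expect_lt(mean(cls$label == "none"), 1)
})

test_that("module identification recovers planted driver units", {
  withr::with_seed(5, {
    specs <- replicate(20, planted_unit_spec("noise", 0, 1), simplify = FALSE)
    ds <- generate_planted_activations(specs, n_steps = 400, seed = NULL,
                                       wire_direction = 1:5, wire_state = 6:10,
                                       logit_noise_sd = 0.05)
    mods <- identify_functional_modules(ds, k = 5)
  })
  expect_equal(mods$vector, 1:5)
  expect_equal(mods$transition, 6:10)
  expect_true(all(mods$unspecialized %in% 11:20))
  expect_true(all(mods$r2$direction_r2 >= 0 & mods$r2$direction_r2 <= 1))
  expect_true(all(mods$r2$state_r2 >= 0 & mods$r2$state_r2 <= 1))

  empty <- identify_functional_modules(ds, k = 0)
  expect_length(empty$vector, 0L)
  expect_error(identify_functional_modules(ds, k = 21), "exceeds")
})

test_that("overlapping top-k units go to the stronger criterion with backfill", {
  # unit 1 drives both logit groups (stronger on direction); with k = 1 it
  # must be claimed by the vector module and the transition module backfills
  withr::with_seed(6, {
    n <- 200
    a1 <- rnorm(n); a2 <- rnorm(n); a3 <- rnorm(n)
    A <- cbind(a1, a2, a3)
    logits <- cbind(matrix(a1, n, 4) + rnorm(4 * n, 0, 0.1),
                    matrix(0.7 * a1 + 0.3 * a2, n, 4) + rnorm(4 * n, 0, 0.1))
    ann <- tibble::tibble(step = 1:n, row = 0L, col = 0L,
                          landmark_adjacent = FALSE, goal_adjacent = FALSE,
                          post_landmark = FALSE, goal_row = NA_integer_,
                          goal_col = NA_integer_, env_id = 1L)
    ds <- activation_dataset(A, ann, logits = logits)
  })
  mods <- identify_functional_modules(ds, k = 1)
  expect_equal(mods$vector, 1L)
  expect_false(1L %in% mods$transition)
})

test_that("lesions zero the chosen units and leave the rest untouched", {
  p <- init_network(seed = 7)
  withr::with_seed(8, obs <- rnorm(48))
  intact <- forward(p, obs)
  empty_lesion <- apply_lesion(p, integer(0))(obs)
  expect_identical(empty_lesion$logits, intact$logits)
  expect_identical(empty_lesion$state, intact$state)

  les <- apply_lesion(p, c(3L, 50L))
  out <- les(obs)
  expect_equal(out$state$c[1, c(3, 50)], c(0, 0))
  expect_equal(out$state$h[1, c(3, 50)], c(0, 0))
  # idempotent: lesioning an already-lesioned state changes nothing
  out2 <- forward(p, obs, lesion = c(3L, 50L))
  expect_identical(out$logits, out2$logits)

  # full lesion: logits reduce to head biases, independent of the observation
  full <- apply_lesion(p, 1:100)
  withr::with_seed(9, {
    l1 <- full(rnorm(48))$logits
    l2 <- full(rnorm(48) * 10)$logits
  })
  expect_identical(l1, l2)
})

test_that("lesioning a hand-wired direction pathway suppresses direction use", {
  # construct a network whose direction logits are driven only by unit 1,
  # which integrates to a positive cell state through biased gates
  net <- network_config()
  p <- init_network(net, seed = 10)
  p$Wx[] <- 0; p$Wh[] <- 0; p$b[] <- 0
  p$b[1] <- 5          # input gate of unit 1 open
  p$b[201] <- 5        # candidate gate of unit 1 saturated positive
  p$b[301] <- 5        # output gate open
  p$P1[] <- 0; p$P1[1, 1] <- 5; p$pb1[] <- 0
  p$P2[] <- 0; p$P2[1, 1] <- 5; p$pb2[] <- 0
  p$P3[] <- 0; p$P3[1, 1:4] <- 10; p$pb3 <- c(rep(0, 4), rep(1, 4))
  task <- task_config(env_kinds = "open", conditions = "both")
  intact <- evaluate(p, 10, task, policy = "greedy", seed = 11)
  lesioned <- evaluate(p, 10, task, policy = "greedy", seed = 11,
                       lesion = 1L)
  expect_equal(strategy_proportions(intact$log)$overall, 1)
  expect_equal(strategy_proportions(lesioned$log)$overall, 0)
})

test_that("paired-seed lesion evaluation reports zero excess for the intact model", {
  p <- init_network(seed = 12)
  out <- evaluate_lesioned(p, list(unspecialized = 1:10), n_trials = 6,
                           seed = 13, env_kinds = "open")
  intact <- out[out$lesion == "intact", ]
  expect_true(all(intact$excess_steps == 0))
  expect_true(all(c("directions_only", "states_only") %in% out$condition))
})

test_that("continuous decoding reads out linearly embedded coordinates", {
  withr::with_seed(14, {
    n <- 600
    row <- sample(0:7, n, TRUE); col <- sample(0:7, n, TRUE)
    A <- cbind(col + rnorm(n, 0, 0.01), row + rnorm(n, 0, 0.01),
               matrix(rnorm(n * 8), n, 8))
    ann <- tibble::tibble(step = 1:n, row = row, col = col,
                          landmark_adjacent = FALSE, goal_adjacent = FALSE,
                          post_landmark = FALSE, goal_row = 3L, goal_col = 4L,
                          env_id = 1L)
    ds <- activation_dataset(A, ann)
  })
  dec <- decode_continuous(ds, 1:10, "current", seed = 15)
  expect_lt(dec$error, 0.05)

  # affine invariance: shifting all activations changes nothing
  ds_shift <- ds; ds_shift$activations <- ds$activations + 5
  expect_equal(decode_continuous(ds_shift, 1:10, "current", seed = 15)$error,
               dec$error)

  # pure noise decodes no better than shuffled targets
  withr::with_seed(16, {
    ds_noise <- ds
    ds_noise$activations <- matrix(rnorm(n * 10), 600, 10)
    real_err <- decode_continuous(ds_noise, 1:10, "current", seed = 17)$error
    shuf_err <- vapply(1:20, function(i) {
      dsp <- ds_noise
      idx <- sample(nrow(dsp$annotations))
      dsp$annotations$row <- dsp$annotations$row[idx]
      dsp$annotations$col <- dsp$annotations$col[idx]
      decode_continuous(dsp, 1:10, "current", seed = 17)$error
    }, numeric(1))
  })
  expect_lt(abs(real_err - mean(shuf_err)), 0.3)
  expect_error(decode_continuous(ds, 1:10, "current", test_frac = 0.2,
                                 seed = 1, alpha = 0.5)$error -> e, NA)
  expect_error(decode_continuous(
    activation_dataset(ds$activations[1:50, ], ds$annotations[1:50, ]),
    1:10, "current"), "100 timesteps")
})

test_that("binary decoding is perfect on separable features and chance on shuffled", {
  withr::with_seed(18, {
    n <- 600
    y <- rep(c(TRUE, FALSE), length.out = n)
    A <- cbind(ifelse(y, 2, -2) + rnorm(n, 0, 0.1),
               matrix(rnorm(n * 5), n, 5))
    ann <- tibble::tibble(step = 1:n, row = 0L, col = 0L,
                          landmark_adjacent = y, goal_adjacent = FALSE,
                          post_landmark = FALSE, goal_row = NA_integer_,
                          goal_col = NA_integer_, env_id = 1L)
    ds <- activation_dataset(A, ann)
  })
  dec <- decode_binary(ds, 1:6, "landmark", seed = 19)
  expect_equal(dec$error, 0)
  expect_equal(dec$n_per_class * 2,
               round((dec$n_test) / 0.2))  # classes balanced before split

  withr::with_seed(20, {
    ds_shuf <- ds
    ds_shuf$annotations$landmark_adjacent <- sample(y)
    errs <- vapply(1:10, function(i)
      decode_binary(ds_shuf, 1:6, "landmark", seed = 20 + i)$error,
      numeric(1))
  })
  expect_lt(abs(mean(errs) - 0.5), 0.12)
  ds_one <- ds; ds_one$annotations$landmark_adjacent <- TRUE
  expect_error(decode_binary(ds_one, 1:6, "landmark"), "absent")
})

test_that("representational PCA is complete, orthogonal, and finds planted planes", {
  withr::with_seed(21, {
    n <- 400
    basis <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
    coords <- matrix(rnorm(n * 2, sd = 3), n, 2)
    A <- coords %*% t(basis) + matrix(rnorm(n * 10, 0, 0.001), n, 10)
    ann <- tibble::tibble(step = 1:n, row = sample(0:7, n, TRUE),
                          col = sample(0:7, n, TRUE),
                          landmark_adjacent = FALSE, goal_adjacent = FALSE,
                          post_landmark = rep(c(TRUE, FALSE), n / 2),
                          goal_row = NA_integer_, goal_col = NA_integer_,
                          env_id = 1L)
    ds <- activation_dataset(A, ann)
  })
  rp <- representational_pca(ds, 1:10)
  expect_gt(sum(rp$variance_explained[1:2]), 0.999)
  V <- rp$pca$rotation
  expect_equal(max(abs(crossprod(V) - diag(ncol(V)))), 0, tolerance = 1e-8)
  recon <- rp$pca$x %*% t(V)
  centered <- scale(ds$activations, center = TRUE, scale = FALSE)
  expect_equal(max(abs(recon - centered)), 0, tolerance = 1e-6)
  expect_error(representational_pca(ds, 1:2), "3 units")
  expect_true(all(c("PC1", "PC2", "PC3") %in% names(rp$centroids)))
})
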