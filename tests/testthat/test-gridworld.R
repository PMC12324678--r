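test_that("cluttered maps place one obstacle per row and per column", {
  for (seed in 1:200) {
    map <- generate_map(seed, "cluttered", 4, "strict")
    expect_equal(nrow(map$obstacles), 8L)
    expect_equal(sort(map$obstacles[, "row"]), 0:7)
    expect_equal(sort(map$obstacles[, "col"]), 0:7)
  }
  open <- generate_map(1, "open", 4, "strict")
  expect_equal(nrow(open$obstacles), 0L)
})

test_that("the identity map is a bijection onto 1..64", {
  for (seed in c(1, 17, 99)) {
    map <- generate_map(seed, "cluttered", 8, "strict")
    expect_identical(sort(as.integer(map$identity)), 1:64)
  }
})

test_that("strict placement keeps landmarks and goal on distinct non-edge free cells", {
  for (seed in 1:50) {
    map <- generate_map(seed, "cluttered", 4, "strict")
    cells <- rbind(map$landmarks[, c("row", "col")], map$goal)
    expect_equal(nrow(unique(cells)), nrow(cells))
    expect_true(all(cells >= 1 & cells <= 6))
    expect_false(any(map$obstacle_grid[cells + 1L]))
  }
})

test_that("exposure allocation splits the 16-click budget", {
  withr::with_seed(1, {
    two <- allocate_landmark_exposures(2, "strict")
    expect_equal(two[, "n_exposures"], c(8L, 8L))
    sixteen <- allocate_landmark_exposures(16, "strict")
    expect_equal(sixteen[, "n_exposures"], rep(1L, 16))
    expect_error(allocate_landmark_exposures(3, "strict"), "divide")
    for (i in 1:50) {
      d2 <- allocate_landmark_exposures(NULL, "day2")
      expect_equal(sum(d2[, "n_exposures"]), 16L)
      expect_true(nrow(d2) >= 2 && nrow(d2) <= 16)
    }
  })
})

test_that("day-2 unique-landmark counts are uniform over 2..16", {
  withr::with_seed(42, {
    counts <- replicate(1000, nrow(allocate_landmark_exposures(NULL, "day2")))
  })
  tab <- table(factor(counts, levels = 2:16))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("exposure schedules alternate fairly and never repeat consecutively", {
  withr::with_seed(5, {
    two <- allocate_landmark_exposures(2, "strict")
    sched <- build_exposure_schedule(two)
    keys <- paste(sched[, 1], sched[, 2])
    expect_true(all(keys == rep(unique(keys), 8)))  # forced strict alternation

    sixteen <- allocate_landmark_exposures(16, "strict")
    s16 <- build_exposure_schedule(sixteen)
    expect_equal(nrow(unique(s16)), 16L)

    for (i in 1:100) {
      four <- allocate_landmark_exposures(4, "strict")
      s4 <- build_exposure_schedule(four)
      k <- paste(s4[, 1], s4[, 2])
      expect_false(any(k[-1] == k[-16]))
      for (round in 0:3)
        expect_equal(sort(unique(k[round * 4 + 1:4])), sort(unique(k)))
    }
  })
})

test_that("BFS distance matches an independent graph oracle", {
  skip_if_not_installed("igraph")
  open <- generate_map(1, "open", 4, "strict")
  expect_equal(shortest_path_distance(open, c(1, 1), c(3, 3)), 4)
  expect_equal(shortest_path_distance(open, c(5, 2), c(5, 2)), 0)
  withr::with_seed(3, {
    for (i in 1:10) {
      map <- generate_map(NULL, "cluttered", 4, "strict")
      free <- which(!map$obstacle_grid, arr.ind = TRUE) - 1L
      for (j in 1:20) {
        ab <- free[sample(nrow(free), 2), ]
        expect_equal(shortest_path_distance(map, ab[1, ], ab[2, ]),
                     bfs_oracle(map, ab[1, ], ab[2, ]))
      }
    }
  })
})

test_that("start cells sit exactly 4 steps from the goal and are eligible", {
  withr::with_seed(11, {
    for (i in 1:150) {
      kind <- if (i %% 2) "open" else "cluttered"
      tr <- generate_trial(NULL, kind, 4)
      expect_equal(shortest_path_distance(tr$map, tr$start, tr$map$goal), 4)
      expect_true(all(tr$start >= 1 & tr$start <= 6))
      expect_false(any(paste(tr$start[1], tr$start[2]) %in%
        paste(tr$map$landmarks[, 1], tr$map$landmarks[, 2])))
      expect_false(all(tr$start == tr$map$goal))
      if (kind == "open")
        expect_equal(sum(abs(tr$start - tr$map$goal)), 4)
    }
  })
})

test_that("modality availability follows the condition rules", {
  expect_equal(unname(available_modalities(episode_config("both"))),
               c(TRUE, TRUE))
  expect_equal(unname(available_modalities(episode_config("directions_only"))),
               c(TRUE, FALSE))
  expect_equal(unname(available_modalities(episode_config("states_only"))),
               c(FALSE, TRUE))
  cfg <- episode_config("random_alternation", p_direction_available = 0.75)
  withr::with_seed(2, {
    draws <- replicate(20000, available_modalities(cfg))
  })
  expect_true(all(colSums(draws) == 1))            # never both nor neither
  freq <- mean(draws["directions", ])
  se <- sqrt(0.75 * 0.25 / 20000)
  expect_lt(abs(freq - 0.75), 3 * se)
})

test_that("steps move, cost points, and the goal pays out", {
  map <- generate_map(1, "open", 4, "strict")
  cfg <- episode_config("both")
  st <- env_reset(map, c(3, 3), cfg)
  res <- env_step(st, map, 4L, cfg)  # E
  expect_equal(res$state$cell, c(3L, 4L))
  expect_equal(res$state$points, 950)
  expect_equal(unname(res$state$last_disp), c(1, 0))  # dx = +1, dy = 0

  # four optimal moves from a distance-4 start end with 1000 - 200 + 1000
  withr::with_seed(4, tr <- generate_trial(NULL, "open", 2))
  st <- env_reset(tr$map, tr$start, cfg)
  for (k in 1:4) {
    d <- tr$map$goal - st$cell
    a <- if (d[1] < 0) 1L else if (d[1] > 0) 2L else if (d[2] < 0) 3L else 4L
    res <- env_step(st, tr$map, a, cfg)
    st <- res$state
  }
  expect_equal(res$event, "goal")
  expect_equal(st$points, 1000 - 200 + 1000)
})

test_that("blocked moves change nothing and cost nothing when unmasked", {
  map <- generate_map(1, "open", 4, "strict")
  cfg <- episode_config("both")
  st <- env_reset(map, c(0, 3), cfg)  # wall to the north
  res <- env_step(st, map, 1L, cfg, masked = FALSE)
  expect_equal(res$event, "blocked")
  expect_equal(res$state$cell, st$cell)
  expect_equal(res$state$points, st$points)
  expect_equal(res$state$step, st$step)
  expect_error(env_step(st, map, 1L, cfg, masked = TRUE), "masked")
})

test_that("episodes truncate at the step cap", {
  map <- generate_map(2, "open", 4, "strict")
  cfg <- episode_config("both", max_steps = 5L)
  st <- env_reset(map, c(0, 0), cfg)
  for (i in 1:5) {
    if (st$done) break
    a <- if (i %% 2) 4L else 3L  # shuttle E/W away from any goal
    res <- env_step(st, map, a, cfg)
    st <- res$state
  }
  expect_true(st$done)
  expect_true(st$truncated || all(st$cell == map$goal))
})

test_that("probe scoring follows the 30/20/10/0 distance bands", {
  expect_equal(score_probe(c(3, 3), c(3, 3)), 30)
  expect_equal(score_probe(c(3, 4), c(3, 3)), 20)
  expect_equal(score_probe(c(4, 4), c(3, 3)), 10)
  expect_equal(score_probe(c(0, 0), c(3, 2)), 0)
  # symmetric and translation invariant
  withr::with_seed(6, {
    for (i in 1:50) {
      a <- sample(0:7, 2); b <- sample(0:7, 2); shift <- sample(-2:2, 2)
      expect_equal(score_probe(a, b), score_probe(b, a))
      expect_equal(score_probe(a + shift, b + shift), score_probe(a, b))
    }
  })
})

test_that("the observation vector is 48 slots in the documented order", {
  withr::with_seed(9, {
    tr <- generate_trial(NULL, "cluttered", 4)
    mem <- build_memory_store(tr$map)
    cfg <- episode_config("both")
    st <- env_reset(tr$map, tr$start, cfg)
    obs <- assemble_observation(st, tr$map, mem, cfg)
    expect_length(obs, 48)
    expect_equal(obs[1:4], c(1, 0, 0, 0))             # 'both' one-hot
    ob <- matrix(obs[5:20], ncol = 2, byrow = TRUE)
    expect_equal(ob[, 1], tr$map$obstacles[, "col"])  # x = column
    expect_equal(ob[, 2], tr$map$obstacles[, "row"])  # y = row
    expect_equal(obs[21:22], c(1, 1))                 # states, directions
    expect_equal(obs[23], observed_identity(tr$map, st$cell))
    expect_equal(obs[28],
                 tr$map$identity[tr$map$goal[1] + 1, tr$map$goal[2] + 1])
    goal_rec <- recall(obs[28], mem)
    expect_equal(obs[39:40], unname(goal_rec[1:2]))   # estimated goal x, y
    expect_equal(obs[46], unname(goal_rec[3]))        # goal confidence
    expect_equal(obs[47:48], c(0, 0))                 # no displacement yet

    # purity: identical inputs give bit-identical vectors
    expect_identical(obs, assemble_observation(st, tr$map, mem, cfg))

    # wall to the north reads as the sentinel 65
    st$cell <- c(0L, 3L)
    expect_equal(assemble_observation(st, tr$map, mem, cfg)[24], 65)

    # open field zeroes all 16 obstacle slots
    tro <- generate_trial(NULL, "open", 4)
    memo <- build_memory_store(tro$map)
    sto <- env_reset(tro$map, tro$start, cfg)
    expect_equal(assemble_observation(sto, tro$map, memo, cfg)[5:20],
                 rep(0, 16))
  })
})

test_that("the action mask permits exactly the traversable, available moves", {
  map <- generate_map(3, "cluttered", 4, "strict")
  cfg <- episode_config("directions_only")
  withr::with_seed(8, {
    tr <- generate_trial(NULL, "cluttered", 4)
    st <- env_reset(tr$map, tr$start, cfg)
    mk <- action_mask(st, tr$map)
    expect_false(any(mk[5:8]))  # state modality unavailable
    for (k in 1:4) {
      dest <- st$cell + metanav:::.DELTAS[k, ]
      traversable <- all(dest >= 0 & dest <= 7) &&
        !tr$map$obstacle_grid[dest[1] + 1, dest[2] + 1]
      expect_equal(mk[k], traversable)
    }
  })
})
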