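# Grid-world task: trial maps, the navigation-phase environment with two
# action modalities (direction moves vs adjacent-state selection), the point
# economy, and the 48-slot observation vector fed to the agent.
#
# Coordinate convention: interior cells are (row, col) in {0..7}^2; the full
# lattice is 10x10 with an implicit wall ring, so any neighbour outside the
# interior is a wall. When coordinate *pairs* are emitted (observations,
# memory estimates, obstacle inputs) x = column and y = row, so y grows
# downward with the row index.

# Displacement deltas for the four cardinal moves, in fixed N, S, W, E order.
.DELTAS <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), nrow = 4, byrow = TRUE,
                  dimnames = list(c("N", "S", "W", "E"), c("dr", "dc")))

.WALL_ID <- 65L

#' Generate one trial's grid world
#'
#' Builds an 8x8 interior world with a shuffled state-identity mapping,
#' optional one-obstacle-per-row-and-column clutter, a goal, and a landmark
#' set with exposure counts summing to 16.
#'
#' @param seed Optional integer seed; the map is reproducible from it.
#' @param environment_kind `"open"` (no interior obstacles) or `"cluttered"`
#'   (exactly 8 obstacles, one per interior row and one per interior column).
#' @param n_unique_landmarks Number of unique landmarks. Under the `"strict"`
#'   variant this must divide the 16-click exposure budget (2, 4, 8 or 16);
#'   under `"day2"` any count in 2..16 is allowed, or `NULL` to draw one
#'   uniformly from 2..16.
#' @param placement_variant `"strict"`: landmarks and goal on distinct
#'   non-edge interior cells, equal exposures. `"day2"`: landmark cells may
#'   lie on the interior edge and the 16 clicks are spread unevenly.
#' @return A `grid_map` list: `interior_size`, `kind`, `variant`, `obstacles`
#'   (n x 2 matrix of (row, col)), `identity` (8x8 integer matrix, a
#'   bijection onto 1..64), `landmarks` (n x 3 matrix: row, col,
#'   n_exposures), `goal` (length-2 vector), plus derived lookups.
#' @export
generate_map <- function(seed = NULL, environment_kind = c("open", "cluttered"),
                         n_unique_landmarks = 4,
                         placement_variant = c("strict", "day2")) {
  environment_kind <- match.arg(environment_kind)
  placement_variant <- match.arg(placement_variant)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- 8L
  obstacle <- matrix(FALSE, n, n)
  if (environment_kind == "cluttered") {
    cols <- sample.int(n) - 1L  # column for each row: a permutation
    obstacle[cbind(seq_len(n), cols + 1L)] <- TRUE
  }

  identity <- matrix(sample.int(64L), n, n)

  lm_alloc <- allocate_landmark_exposures(n_unique_landmarks, placement_variant,
                                          obstacle = obstacle)

  # Goal: non-edge, non-obstacle, not a landmark (all variants).
  elig <- .eligible_cells(obstacle, edge_ok = FALSE)
  taken <- paste(lm_alloc[, 1], lm_alloc[, 2])
  elig <- elig[!(paste(elig[, 1], elig[, 2]) %in% taken), , drop = FALSE]
  if (nrow(elig) == 0L)
    stop("no eligible goal cell: map placement impossible")
  goal <- elig[sample.int(nrow(elig), 1L), ]

  interior_ids <- identity
  interior_ids[obstacle] <- .WALL_ID
  id_lattice <- matrix(.WALL_ID, n + 2L, n + 2L)
  id_lattice[2:(n + 1L), 2:(n + 1L)] <- interior_ids
  open_lattice <- matrix(FALSE, n + 2L, n + 2L)
  open_lattice[2:(n + 1L), 2:(n + 1L)] <- !obstacle
  map <- list(
    interior_size = n,
    kind = environment_kind,
    variant = placement_variant,
    obstacles = which(obstacle, arr.ind = TRUE) - 1L,
    obstacle_grid = obstacle,
    identity = identity,
    id_lattice = id_lattice,
    open_lattice = open_lattice,
    landmarks = lm_alloc,
    goal = as.integer(goal)
  )
  colnames(map$obstacles) <- c("row", "col")
  # sorted row-major for the deterministic obstacle-coordinate input
  if (nrow(map$obstacles) > 0L)
    map$obstacles <- map$obstacles[order(map$obstacles[, 1], map$obstacles[, 2]), ,
                                   drop = FALSE]
  class(map) <- "grid_map"
  map
}

.eligible_cells <- function(obstacle, edge_ok) {
  n <- nrow(obstacle)
  rng <- if (edge_ok) 0:(n - 1L) else 1:(n - 2L)
  cells <- as.matrix(expand.grid(row = rng, col = rng))
  free <- !obstacle[cells + 1L]
  cells[free, , drop = FALSE]
}

#' Allocate the 16-click landmark exposure budget
#'
#' Chooses landmark cells and splits the fixed budget of 16 map-reading
#' exposures across them. Under `"strict"` each of the `n_unique` landmarks
#' (which must divide 16) receives `16 / n_unique` exposures on distinct
#' non-edge cells. Under `"day2"` the unique count may be any value in 2..16
#' (drawn uniformly when `NULL`), cells may lie on the interior edge, and the
#' remaining clicks are spread uniformly at random.
#'
#' @param n_unique Unique landmark count, or `NULL` (day2 only) to draw it.
#' @param variant `"strict"` or `"day2"`.
#' @param obstacle Optional 8x8 logical obstacle grid (default: open field).
#' @return Integer matrix with columns `row`, `col`, `n_exposures`; exposure
#'   counts always sum to 16.
#' @export
allocate_landmark_exposures <- function(n_unique, variant = c("strict", "day2"),
                                        obstacle = matrix(FALSE, 8, 8)) {
  variant <- match.arg(variant)
  budget <- 16L
  if (variant == "strict") {
    n_unique <- as.integer(n_unique)
    if (budget %% n_unique != 0L)
      stop("strict variant requires n_unique to divide the 16-exposure budget")
    elig <- .eligible_cells(obstacle, edge_ok = FALSE)
    if (nrow(elig) < n_unique) stop("not enough free non-edge cells for landmarks")
    cells <- elig[sample.int(nrow(elig), n_unique), , drop = FALSE]
    expo <- rep.int(budget %/% n_unique, n_unique)
  } else {
    if (is.null(n_unique)) n_unique <- sample(2:16, 1L)
    n_unique <- as.integer(n_unique)
    if (n_unique < 2L || n_unique > budget) stop("day2 n_unique must lie in 2..16")
    elig <- .eligible_cells(obstacle, edge_ok = TRUE)
    cells <- elig[sample.int(nrow(elig), n_unique), , drop = FALSE]
    expo <- rep.int(1L, n_unique)
    extra <- tabulate(sample.int(n_unique, budget - n_unique, replace = TRUE),
                      nbins = n_unique)
    expo <- expo + extra
  }
  out <- cbind(cells, n_exposures = as.integer(expo))
  rownames(out) <- NULL
  out
}

#' Order the 16 landmark exposures of a map-reading phase
#'
#' Produces the click sequence shown to a learner: no landmark appears twice
#' consecutively, and every unique landmark is shown once per round before
#' any repeats (the sequence is a concatenation of rounds, each a permutation
#' of the landmark set).
#'
#' @param landmarks Landmark matrix from [allocate_landmark_exposures()]
#'   (strict variant: equal exposure counts).
#' @return Integer matrix of 16 rows, columns `row`, `col`, in display order.
#' @export
build_exposure_schedule <- function(landmarks) {
  expo <- landmarks[, "n_exposures"]
  if (length(unique(expo)) != 1L)
    stop("exposure schedule requires equal per-landmark exposures (strict variant)")
  n <- nrow(landmarks)
  rounds <- expo[1]
  seq_idx <- integer(0)
  last <- 0L
  for (r in seq_len(rounds)) {
    repeat {
      perm <- sample.int(n)
      if (n == 1L || perm[1] != last) break
    }
    seq_idx <- c(seq_idx, perm)
    last <- perm[n]
  }
  landmarks[seq_idx, c("row", "col"), drop = FALSE]
}

#' Breadth-first shortest-path distance between two interior cells
#'
#' Path length under 4-neighbour moves avoiding obstacles and the wall ring;
#' equals Manhattan distance on open maps.
#'
#' @param map A `grid_map`.
#' @param a,b Length-2 (row, col) interior cells; both must be traversable.
#' @return Non-negative integer, or `Inf` if `b` is unreachable from `a`.
#' @export
shortest_path_distance <- function(map, a, b) {
  d <- .bfs_distances(map$obstacle_grid, a)
  d[b[1] + 1L, b[2] + 1L]
}

# All-cell BFS distance matrix from one source (internal; the analysis-side
# oracle in the tests re-derives distances independently).
.bfs_distances <- function(obstacle, from) {
  n <- nrow(obstacle)
  if (obstacle[from[1] + 1L, from[2] + 1L]) stop("BFS source is not traversable")
  dist <- matrix(Inf, n, n)
  dist[from[1] + 1L, from[2] + 1L] <- 0
  queue_r <- integer(n * n); queue_c <- integer(n * n)
  queue_r[1] <- from[1]; queue_c[1] <- from[2]
  head <- 1L; tail <- 1L
  while (head <= tail) {
    r <- queue_r[head]; c <- queue_c[head]; head <- head + 1L
    d0 <- dist[r + 1L, c + 1L]
    for (k in 1:4) {
      nr <- r + .DELTAS[k, 1L]; nc <- c + .DELTAS[k, 2L]
      if (nr < 0L || nr >= n || nc < 0L || nc >= n) next
      if (obstacle[nr + 1L, nc + 1L]) next
      if (is.finite(dist[nr + 1L, nc + 1L])) next
      dist[nr + 1L, nc + 1L] <- d0 + 1
      tail <- tail + 1L
      queue_r[tail] <- nr; queue_c[tail] <- nc
    }
  }
  dist
}

#' Choose a navigation start cell
#'
#' Start cells sit exactly 4 path-steps from the goal and are never a
#' landmark, the goal, an obstacle, or an edge cell.
#'
#' @param map A `grid_map`.
#' @return Length-2 (row, col) start cell.
#' @export
choose_start <- function(map) {
  d <- .bfs_distances(map$obstacle_grid, map$goal)
  cand <- .eligible_cells(map$obstacle_grid, edge_ok = FALSE)
  taken <- rbind(map$landmarks[, c("row", "col"), drop = FALSE],
                 matrix(map$goal, 1))
  keep <- !(paste(cand[, 1], cand[, 2]) %in% paste(taken[, 1], taken[, 2]))
  cand <- cand[keep, , drop = FALSE]
  at4 <- d[cand + 1L] == 4
  cand <- cand[at4, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop(structure(class = c("metanav_no_start", "error", "condition"),
                   list(message = "no eligible start cell at distance 4; regenerate the map",
                        call = sys.call())))
  as.integer(cand[sample.int(nrow(cand), 1L), ])
}

#' Generate a complete trial (map + start), regenerating impossible maps
#'
#' @param seed Optional seed.
#' @param max_attempts Regeneration cap when no distance-4 start exists.
#' @inheritParams generate_map
#' @return List with `map` and `start`.
#' @export
generate_trial <- function(seed = NULL, environment_kind = "open",
                           n_unique_landmarks = 4, placement_variant = "strict",
                           max_attempts = 100L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(max_attempts)) {
    map <- generate_map(NULL, environment_kind, n_unique_landmarks,
                        placement_variant)
    start <- tryCatch(choose_start(map), metanav_no_start = function(e) NULL)
    if (!is.null(start)) return(list(map = map, start = start))
  }
  stop("no feasible trial after ", max_attempts, " map regenerations")
}

#' Episode configuration
#'
#' @param condition One of `"both"`, `"directions_only"`, `"states_only"`,
#'   `"random_alternation"`.
#' @param p_direction_available Probability that the direction modality is
#'   the available one on a `random_alternation` step (0.75 open field,
#'   0.50 cluttered, matching pilot human direction-use rates).
#' @param max_steps Step cap after which an episode is truncated.
#' @param step_cost,goal_reward Point economy: each step costs 50 points and
#'   the goal is worth 1,000; trials start with 1,000 points.
#' @export
episode_config <- function(condition = c("both", "directions_only",
                                         "states_only", "random_alternation"),
                           p_direction_available = 0.75,
                           max_steps = 200L, step_cost = 50,
                           goal_reward = 1000, start_points = 1000) {
  condition <- match.arg(condition)
  stopifnot(p_direction_available >= 0, p_direction_available <= 1,
            max_steps > 0)
  list(condition = condition,
       p_direction_available = p_direction_available,
       max_steps = as.integer(max_steps),
       step_cost = step_cost, goal_reward = goal_reward,
       start_points = start_points)
}

#' Draw the per-step modality availability flags
#'
#' @param config An [episode_config()].
#' @return Named logical vector `c(directions = , states = )`. Under
#'   `random_alternation` exactly one modality is available, the direction
#'   modality with probability `p_direction_available`.
#' @export
available_modalities <- function(config) {
  switch(config$condition,
    both = c(directions = TRUE, states = TRUE),
    directions_only = c(directions = TRUE, states = FALSE),
    states_only = c(directions = FALSE, states = TRUE),
    random_alternation = {
      dir <- stats::runif(1) < config$p_direction_available
      c(directions = dir, states = !dir)
    })
}

#' Reset the navigation environment
#'
#' @param map A `grid_map`.
#' @param start Start cell (row, col).
#' @param config An [episode_config()].
#' @return An `env_state` list: current cell, step index, points balance,
#'   visited-cell grid, last displacement and this step's modality flags.
#' @export
env_reset <- function(map, start, config) {
  visited <- matrix(FALSE, map$interior_size, map$interior_size)
  visited[start[1] + 1L, start[2] + 1L] <- TRUE
  structure(list(
    cell = as.integer(start),
    step = 0L,
    points = config$start_points,
    visited = visited,
    last_disp = c(dx = 0, dy = 0),
    modalities = available_modalities(config),
    done = FALSE, truncated = FALSE
  ), class = "env_state")
}

#' Valid-action mask for the current step
#'
#' Actions 1..4 are direction moves (N, S, W, E), 5..8 select the adjacent
#' state in the same slot order. An action is valid iff its modality is
#' available this step and its target cell is traversable.
#'
#' @return Logical vector of length 8.
#' @export
action_mask <- function(state, map) {
  # linear index of the current cell in the (n+2)^2 walled lattice,
  # neighbour offsets in N, S, W, E order
  np2 <- map$interior_size + 2L
  lin <- (state$cell[2] + 1L) * np2 + state$cell[1] + 2L
  ok <- map$open_lattice[lin + c(-1L, 1L, -np2, np2)]
  c(ok & state$modalities[["directions"]], ok & state$modalities[["states"]])
}

#' Advance the environment by one action
#'
#' Valid moves update the position, cost `step_cost` points and record the
#' displacement; blocked moves (reachable only with masking disabled) change
#' nothing and cost nothing, mirroring the human rule that clicks toward an
#' obstacle had no effect. Reaching the goal pays `goal_reward` and ends the
#' episode; hitting `max_steps` truncates it.
#'
#' @param state An `env_state`. @param map A `grid_map`.
#' @param action Integer 1..8. @param config An [episode_config()].
#' @param masked If `TRUE` (the default, as during agent training) taking an
#'   invalid action is a contract violation.
#' @return List `(state, event)` with `event` one of `"moved"`, `"blocked"`,
#'   `"goal"`, `"truncated"`.
#' @export
env_step <- function(state, map, action, config, masked = TRUE, mask = NULL) {
  if (action < 1L || action > 8L) stop("action index must be in 1..8")
  if (state$done) stop("episode already finished")
  if (is.null(mask)) mask <- action_mask(state, map)
  if (!mask[action]) {
    if (masked) stop("masked invalid action taken: contract violation")
    state$step <- state$step  # blocked: no cost, no movement, no step count
    return(list(state = state, event = "blocked"))
  }
  k <- ((action - 1L) %% 4L) + 1L
  state$cell <- as.integer(state$cell + .DELTAS[k, ])
  state$step <- state$step + 1L
  state$points <- state$points - config$step_cost
  state$last_disp <- c(dx = .DELTAS[k, 2L], dy = .DELTAS[k, 1L])
  state$visited[state$cell[1] + 1L, state$cell[2] + 1L] <- TRUE
  event <- "moved"
  if (all(state$cell == map$goal)) {
    state$points <- state$points + config$goal_reward
    state$done <- TRUE
    event <- "goal"
  } else if (state$step >= config$max_steps) {
    state$done <- TRUE; state$truncated <- TRUE
    event <- "truncated"
  } else {
    state$modalities <- available_modalities(config)
  }
  list(state = state, event = event)
}

#' Observed identity of a lattice cell
#'
#' Walls and obstacles read as the sentinel 65; every other interior cell
#' reads as its unique shuffled identity in 1..64.
#' @export
observed_identity <- function(map, cell) {
  n <- map$interior_size
  r <- cell[1]; c <- cell[2]
  if (r < -1L || r > n || c < -1L || c > n) return(.WALL_ID)
  map$id_lattice[r + 2L, c + 2L]
}

#' Score a memory-probe placement
#'
#' 30 points for the correct cell, 20 one grid step away, 10 two steps away,
#' 0 beyond two steps (grid steps = Manhattan distance).
#' @export
score_probe <- function(response_cell, true_cell) {
  d <- sum(abs(response_cell - true_cell))
  if (d == 0) 30 else if (d == 1) 20 else if (d == 2) 10 else 0
}

.CONDITIONS <- c("both", "directions_only", "states_only", "random_alternation")

#' Assemble the 48-slot observation vector
#'
#' Concatenates, in order: condition one-hot (4); obstacle x,y pairs sorted
#' row-major (16, zeros in the open field); state-modality and
#' direction-modality availability flags (2); current, four adjacent (N, S,
#' W, E) and goal state identities (6, sentinel 65 for walls/obstacles);
#' remembered x,y estimates for the same six states (12, zeros where no
#' memory exists); the noise s.d. used for each estimate as a confidence
#' signal (6); and the last step's (dx, dy) displacement (2).
#'
#' @param state An `env_state`. @param map A `grid_map`.
#' @param memory A [build_memory_store()] result.
#' @param config An [episode_config()].
#' @return Numeric vector of length 48.
#' @export
assemble_observation <- function(state, map, memory, config) {
  base <- .obs_base(map, config)
  .obs_fill(base, state, map, memory)
}

# Static observation slots 1-20 (condition one-hot + obstacle coordinates),
# constant within an episode; cached by the rollout and evaluation loops.
.obs_base <- function(map, config) {
  obs <- numeric(48)
  obs[match(config$condition, .CONDITIONS)] <- 1
  if (nrow(map$obstacles) > 0L) {
    # (x, y) = (col, row) per pair, pairs sorted row-major
    obs[5:20] <- as.numeric(t(map$obstacles[, c("col", "row")]))
  }
  obs
}

# Dynamic slots 21-48.
.obs_fill <- function(obs, state, map, memory) {
  obs[21] <- as.numeric(state$modalities[["states"]])
  obs[22] <- as.numeric(state$modalities[["directions"]])
  r <- state$cell[1] + 2L; c <- state$cell[2] + 2L
  g <- map$id_lattice
  ids <- c(g[r, c], g[r - 1L, c], g[r + 1L, c], g[r, c - 1L], g[r, c + 1L],
           map$identity[map$goal[1] + 1L, map$goal[2] + 1L])
  obs[23:28] <- ids
  rec <- unclass(memory)[ids, ]       # 6 x 3: est_x, est_y, sd
  obs[29:40] <- as.numeric(t(rec[, 1:2]))
  obs[41:46] <- rec[, 3]
  obs[47] <- state$last_disp[["dx"]]
  obs[48] <- state$last_disp[["dy"]]
  obs
}
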