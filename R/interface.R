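# Orchestration and file I/O: a seeded multi-stage pipeline runner with a
# manifest, JSON-lines trajectory logs (streamable, human-inspectable), JSON
# map serialisation, and tidy CSV exports for downstream statistics tooling.

.TRAJ_FIELDS <- c("trial", "step", "row", "col", "action", "modality",
                  "dest_type", "visited_before", "points", "event",
                  "condition", "env_kind", "n_landmarks")

#' Write a trajectory log as JSON lines
#'
#' One JSON object per step record; lossless round trip with
#' [read_trajectories()].
#' @param log Trajectory tibble. @param path Output file.
#' @export
write_trajectories <- function(log, path) {
  unknown <- setdiff(names(log), .TRAJ_FIELDS)
  if (length(unknown))
    stop("unknown trajectory field(s): ", paste(unknown, collapse = ", "))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  invisible(path)
}

#' Read a JSON-lines trajectory log
#'
#' @param path File written by [write_trajectories()].
#' @return Trajectory tibble. Records with unknown fields are rejected with
#'   an error naming the offending field.
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    unknown <- setdiff(names(rec), .TRAJ_FIELDS)
    if (length(unknown))
      stop("unknown trajectory field(s): ", paste(unknown, collapse = ", "))
    rec[vapply(rec, is.null, logical(1))] <- NA
    tibble::as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  for (col in c("trial", "step", "row", "col", "action"))
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  out
}

#' Serialise a grid map to JSON
#' @export
write_map <- function(map, path) {
  row_pairs <- function(m) lapply(seq_len(nrow(m)),
                                  function(i) unname(m[i, ]))
  obj <- list(interior_size = map$interior_size,
              obstacles = row_pairs(map$obstacles),
              identity = as.integer(map$identity),
              landmarks = row_pairs(map$landmarks),
              goal = map$goal, kind = map$kind, variant = map$variant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid map from JSON
#' @export
read_map <- function(path) {
  obj <- jsonlite::fromJSON(path)
  n <- obj$interior_size
  as_rows <- function(x, cols) {
    m <- if (is.matrix(x)) x
         else matrix(as.integer(unlist(x)), ncol = length(cols), byrow = TRUE)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, cols)
    m
  }
  obstacles <- if (length(obj$obstacles))
    as_rows(obj$obstacles, c("row", "col"))
  else matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  obstacle_grid <- matrix(FALSE, n, n)
  if (nrow(obstacles)) obstacle_grid[obstacles + 1L] <- TRUE
  landmarks <- as_rows(obj$landmarks, c("row", "col", "n_exposures"))
  identity <- matrix(as.integer(obj$identity), n, n)
  interior_ids <- identity
  interior_ids[obstacle_grid] <- 65L
  id_lattice <- matrix(65L, n + 2L, n + 2L)
  id_lattice[2:(n + 1L), 2:(n + 1L)] <- interior_ids
  open_lattice <- matrix(FALSE, n + 2L, n + 2L)
  open_lattice[2:(n + 1L), 2:(n + 1L)] <- !obstacle_grid
  structure(list(interior_size = n, kind = obj$kind, variant = obj$variant,
                 obstacles = obstacles, obstacle_grid = obstacle_grid,
                 identity = identity, id_lattice = id_lattice,
                 open_lattice = open_lattice,
                 landmarks = landmarks, goal = as.integer(obj$goal)),
            class = "grid_map")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, threading stage
#' outputs forward, writing versioned artifacts under `out_dir`, and
#' recording every seed in a JSON manifest. Stages: `train` (desk-scale PPO
#' run), `evaluate` (greedy trajectories of the trained agent), `behavior`
#' (strategy and performance summaries), `units` (activation recording,
#' classification and module identification), `sampling` (synthetic
#' sampling strategies, metrics and PCA).
#'
#' @param stages Character vector of stage names.
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; per-stage seeds derive from it and are recorded.
#' @param ppo,task,net,noise Stage configurations.
#' @param n_eval_trials,n_trials_per_env,n_subjects Problem sizes.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(stages = c("train", "evaluate", "behavior", "units",
                                    "sampling"),
                         out_dir = "results", seed = 1L,
                         ppo = ppo_config(), task = task_config(),
                         net = network_config(),
                         noise = memory_noise_params(),
                         n_eval_trials = 400L, n_trials_per_env = 100L,
                         n_subjects = 50L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(global = seed, train = seed, evaluate = seed + 1L,
                units = seed + 2L, sampling = seed + 3L)
  artifacts <- list()
  model <- NULL

  if ("train" %in% stages) {
    model <- train(task, net, ppo, seed = seeds$train, noise = noise)
    utils::write.csv(model$curve, file.path(out_dir, "training_curve.csv"),
                     row.names = FALSE)
    saveRDS(model$params, file.path(out_dir, "params.rds"))
    artifacts$training_curve <- "training_curve.csv"
  }
  ev <- NULL
  if ("evaluate" %in% stages) {
    if (is.null(model)) stop("evaluate stage requires the train stage's model")
    ev <- evaluate(model$params, n_eval_trials, task, policy = "greedy",
                   seed = seeds$evaluate, noise = noise)
    write_trajectories(ev$log, file.path(out_dir, "trajectories.jsonl"))
    utils::write.csv(ev$trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    artifacts$trajectories <- "trajectories.jsonl"
  }
  if ("behavior" %in% stages) {
    if (is.null(ev)) stop("behavior stage requires the evaluate stage's log")
    sp <- strategy_proportions(ev$log)
    utils::write.csv(sp$by_cell, file.path(out_dir, "strategy_table.csv"),
                     row.names = FALSE)
    st <- steps_to_goal_stats(ev$trials, "condition", n_boot = 2000L,
                              seed = seeds$evaluate)
    utils::write.csv(st, file.path(out_dir, "steps_to_goal.csv"),
                     row.names = FALSE)
    artifacts$strategy_table <- "strategy_table.csv"
  }
  if ("units" %in% stages) {
    if (is.null(model)) stop("units stage requires the train stage's model")
    ds <- record_activations(model$params, n_trials_per_env,
                             seed = seeds$units)
    cls <- classify_units(ds)
    utils::write.csv(cls, file.path(out_dir, "unit_labels.csv"),
                     row.names = FALSE)
    mods <- identify_functional_modules(ds)
    utils::write.csv(mods$r2, file.path(out_dir, "module_r2.csv"),
                     row.names = FALSE)
    artifacts$unit_labels <- "unit_labels.csv"
  }
  if ("sampling" %in% stages) {
    set.seed(seeds$sampling)
    mat <- simulate_sampling_strategies("mixture", n_subjects)
    pca <- sampling_pca(mat)
    utils::write.csv(mat, file.path(out_dir, "sampling_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(subject = seq_len(nrow(mat)), pca$scores),
                     file.path(out_dir, "sampling_scores.csv"),
                     row.names = FALSE)
    artifacts$sampling_matrix <- "sampling_matrix.csv"
  }
  manifest <- list(stages = stages, seeds = seeds, artifacts = artifacts,
                   config = list(ppo_scale = ppo$scale,
                                 n_envs = ppo$n_envs, n_steps = ppo$n_steps,
                                 n_updates = ppo$n_updates))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
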