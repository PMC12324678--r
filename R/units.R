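# Unit-level analyses of the recurrent network: spatial/landmark/conjunctive
# response classification via a two-factor ANOVA over smoothed activation
# maps, identification of the 'vector' and 'transition' functional modules by
# variance explained in the action logits, lesioning, position/adjacency
# decoding, and representational-geometry PCA.

#' Bundle an activation dataset
#'
#' @param activations Timesteps x units cell-state matrix.
#' @param annotations Tibble aligned with the rows of `activations`
#'   (position, adjacency flags, environment id, goal location).
#' @param logits Timesteps x 8 policy-logit matrix.
#' @param layouts Named list, environment id -> landmark-cell matrix.
#' @export
activation_dataset <- function(activations, annotations, logits = NULL,
                               layouts = NULL) {
  stopifnot(nrow(activations) == nrow(annotations))
  structure(list(activations = activations, annotations = annotations,
                 logits = logits, layouts = layouts),
            class = "activation_dataset")
}

#' The four fixed two-landmark classification environments
#'
#' Landmark pairs at ((2,2),(5,5)), ((2,5),(5,2)), ((2,2),(5,2)) and
#' ((2,5),(5,5)) in interior (row, col) coordinates.
#' @export
classification_layouts <- function() {
  list(`1` = rbind(c(2L, 2L), c(5L, 5L)),
       `2` = rbind(c(2L, 5L), c(5L, 2L)),
       `3` = rbind(c(2L, 2L), c(5L, 2L)),
       `4` = rbind(c(2L, 5L), c(5L, 5L)))
}

#' Record cell-state activations over the classification environment suite
#'
#' Runs greedy evaluation on each fixed two-landmark environment and logs
#' per-step cell states, policy logits and annotations.
#'
#' @param params Trained network parameters.
#' @param n_trials_per_env Trials per environment.
#' @param seed Integer seed.
#' @param layouts Landmark layouts (default [classification_layouts()]).
#' @param condition Action condition used during recording.
#' @return An [activation_dataset()].
#' @export
record_activations <- function(params, n_trials_per_env = 1000L, seed = 1L,
                               layouts = classification_layouts(),
                               condition = "both") {
  set.seed(as.integer(seed))
  parts <- lapply(seq_along(layouts), function(e) {
    evaluate(params, n_trials_per_env,
             task_config(env_kinds = "open", conditions = condition,
                         n_landmarks = nrow(layouts[[e]])),
             policy = "greedy", record_activations = TRUE,
             fixed_landmarks = layouts[[e]], env_id = e)
  })
  activation_dataset(
    activations = do.call(rbind, lapply(parts, `[[`, "activations")),
    annotations = dplyr::bind_rows(lapply(parts, `[[`, "annotations")),
    logits = do.call(rbind, lapply(parts, `[[`, "logits")),
    layouts = layouts)
}

# Separable Gaussian filter with half-sample symmetric (reflective) boundary.
gaussian_smooth <- function(mat, sigma = 0.7) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1d <- function(x) {
    n <- length(x)
    pad <- c(x[r:1], x, x[n:(n - r + 1)])
    vapply(seq_len(n), function(i) sum(pad[i:(i + 2 * r)] * k), numeric(1))
  }
  out <- apply(mat, 2, smooth1d)            # columns (within-column = rows)
  t(apply(out, 1, smooth1d))
}

#' Per-environment spatial activation maps of one unit
#'
#' Mean cell-state activation at each of the 64 interior locations per
#' environment, Gaussian-smoothed (sigma = 0.7 cell units, reflective
#' boundary). Cells never visited in an environment are imputed with the
#' unit's grand mean there before smoothing.
#'
#' @param dataset An [activation_dataset()]. @param unit Unit index.
#' @param sigma Smoothing s.d. in cell units (0 disables smoothing).
#' @return List of 8x8 matrices, one per environment id.
#' @export
unit_spatial_maps <- function(dataset, unit, sigma = 0.7) {
  ann <- dataset$annotations
  act <- dataset$activations[, unit]
  envs <- sort(unique(ann$env_id))
  lapply(stats::setNames(envs, envs), function(e) {
    sel <- ann$env_id == e
    m <- matrix(NA_real_, 8, 8)
    sums <- tapply(act[sel], list(ann$row[sel], ann$col[sel]), mean)
    m[cbind(as.integer(rownames(sums))[row(sums)] + 1L,
            as.integer(colnames(sums))[col(sums)] + 1L)] <- sums
    m[is.na(m)] <- mean(act[sel])
    gaussian_smooth(m, sigma)
  })
}

# Quadrant (4x4 block) factor and on-or-adjacent-to-landmark factor for the
# 64 cells of one environment layout.
.cell_factors <- function(layout) {
  cells <- expand.grid(row = 0:7, col = 0:7)
  quadrant <- paste0(ifelse(cells$row < 4, "top", "bottom"),
                     ifelse(cells$col < 4, "_left", "_right"))
  near <- vapply(seq_len(nrow(cells)), function(i)
    any(abs(layout[, 1] - cells$row[i]) + abs(layout[, 2] - cells$col[i]) <= 1),
    logical(1))
  data.frame(row = cells$row, col = cells$col,
             quadrant = factor(quadrant), landmark = factor(near))
}

#' Classify units as spatial, landmark, conjunctive or none
#'
#' For each unit, builds the 256-point table of smoothed mean activations
#' (64 cells x 4 environments) and fits a two-factor ANOVA with quadrant
#' (four 4x4 blocks) and on-or-adjacent-to-landmark (4-neighbourhood)
#' factors. Labels: `spatial` if only the quadrant main effect is
#' significant, `landmark` if only the landmark main effect, `conjunctive`
#' if both main effects and/or the interaction are significant, `none`
#' otherwise (alpha = 0.05, uncorrected).
#'
#' @param dataset An [activation_dataset()] with `layouts`.
#' @param sigma Map-smoothing s.d. @param alpha Significance level.
#' @return Tibble: `unit`, `label`, and the three p-values.
#' @export
classify_units <- function(dataset, sigma = 0.7, alpha = 0.05) {
  layouts <- dataset$layouts
  if (is.null(layouts)) stop("dataset carries no landmark layouts")
  factors <- lapply(layouts, .cell_factors)
  n_units <- ncol(dataset$activations)
  out <- lapply(seq_len(n_units), function(u) {
    maps <- unit_spatial_maps(dataset, u, sigma)
    tab <- dplyr::bind_rows(lapply(names(layouts), function(e) {
      f <- factors[[e]]
      f$resp <- maps[[e]][cbind(f$row + 1L, f$col + 1L)]
      f$env <- e
      f
    }))
    ps <- tryCatch({
      fit <- stats::aov(resp ~ quadrant * landmark, data = tab)
      sm <- summary(fit)[[1]][["Pr(>F)"]]
      c(sm[1], sm[2], sm[3])
    }, error = function(e) rep(NA_real_, 3))
    label <- if (any(!is.finite(ps))) "none"
      else {
        q <- ps[1] < alpha; l <- ps[2] < alpha; i <- ps[3] < alpha
        if ((q && l) || i) "conjunctive"
        else if (q) "spatial" else if (l) "landmark" else "none"
      }
    tibble::tibble(unit = u, label = label, p_quadrant = ps[1],
                   p_landmark = ps[2], p_interaction = ps[3])
  })
  dplyr::bind_rows(out)
}

#' Identify 'vector' and 'transition' functional modules
#'
#' Regresses each unit's cell-state activations onto each of the 8 action
#' logits, averages the R-squared values over the 4 direction logits and
#' over the 4 state logits, and takes the top `k` units per criterion
#' ('vector' and 'transition' modules) plus the bottom `k` on the maximum
#' of both ('unspecialized'). A unit in both top-k sets is assigned to the
#' criterion where it explains more variance and the other set is backfilled
#' from its next-ranked unit; ties break toward the lower unit index.
#'
#' @param dataset An [activation_dataset()] with logits.
#' @param k Units per module (the methods text says 10; one figure caption
#'   says 20 — configurable for that reason).
#' @return List `vector`, `transition`, `unspecialized` (integer index
#'   vectors) and `r2` (tibble of per-unit mean R-squared values).
#' @export
identify_functional_modules <- function(dataset, k = 10L) {
  if (is.null(dataset$logits)) stop("dataset carries no action logits")
  A <- dataset$activations; L <- dataset$logits
  n_units <- ncol(A)
  if (k > n_units) stop("k exceeds the number of units")
  r2 <- stats::cor(A, L)^2                  # simple-regression R^2 = cor^2
  r2[is.na(r2)] <- 0                        # constant unit or logit
  dir_r2 <- rowMeans(r2[, 1:4, drop = FALSE])
  sta_r2 <- rowMeans(r2[, 5:8, drop = FALSE])
  if (k == 0L) {
    return(list(vector = integer(0), transition = integer(0),
                unspecialized = integer(0),
                r2 = tibble::tibble(unit = seq_len(n_units),
                                    direction_r2 = dir_r2, state_r2 = sta_r2)))
  }
  dir_rank <- order(-dir_r2, seq_len(n_units))
  sta_rank <- order(-sta_r2, seq_len(n_units))
  vec <- dir_rank[seq_len(k)]; tra <- sta_rank[seq_len(k)]
  repeat {
    ov <- intersect(vec, tra)
    if (!length(ov)) break
    for (u in ov) {
      if (dir_r2[u] >= sta_r2[u]) {         # keep in vector, backfill transition
        tra <- setdiff(tra, u)
        nxt <- setdiff(sta_rank, c(tra, vec))[1]
        tra <- c(tra, nxt)
      } else {
        vec <- setdiff(vec, u)
        nxt <- setdiff(dir_rank, c(vec, tra))[1]
        vec <- c(vec, nxt)
      }
    }
  }
  unspec_rank <- order(pmax(dir_r2, sta_r2), seq_len(n_units))
  unspec <- unspec_rank[seq_len(k)]
  list(vector = sort(vec), transition = sort(tra), unspecialized = sort(unspec),
       r2 = tibble::tibble(unit = seq_len(n_units),
                           direction_r2 = dir_r2, state_r2 = sta_r2))
}

#' Lesion a unit set
#'
#' Returns a forward function in which the cell and hidden states of the
#' chosen units are forced to zero at every timestep before any downstream
#' use. Lesioning the empty set is bit-identical to the intact network.
#'
#' @param params Network parameters. @param unit_set Integer unit indices.
#' @return `function(observation, state = NULL)` behaving like [forward()].
#' @export
apply_lesion <- function(params, unit_set) {
  nr <- attr(params, "config")$n_recurrent
  unit_set <- as.integer(unit_set)
  stopifnot(all(unit_set >= 1L & unit_set <= nr))
  function(observation, state = NULL)
    forward(params, observation, state, lesion = unit_set)
}

#' Evaluate lesioned models against the intact model
#'
#' Runs paired-seed evaluations (identical trial streams) of the intact
#' network and each lesioned module on the `directions_only` and
#' `states_only` conditions in both environment kinds, plus the `both`
#' condition to measure the strategy-use shift.
#'
#' @param params Network parameters.
#' @param modules Named list of unit-index sets (e.g., from
#'   [identify_functional_modules()]).
#' @param n_trials Trials per (lesion x condition block).
#' @param seed Paired evaluation seed.
#' @param env_kinds Environment kinds crossed into the evaluation.
#' @return Tibble with per-lesion, per-condition mean steps-to-goal, the
#'   excess over intact, and direction-use proportion in the `both`
#'   condition.
#' @export
evaluate_lesioned <- function(params, modules, n_trials = 200L, seed = 1L,
                              env_kinds = c("open", "cluttered")) {
  lesions <- c(list(intact = integer(0)), modules)
  run <- function(lesion) {
    forced <- evaluate(params, n_trials,
                       task_config(env_kinds = env_kinds,
                                   conditions = c("directions_only",
                                                  "states_only")),
                       policy = "greedy", seed = seed, lesion = lesion)
    both <- evaluate(params, n_trials,
                     task_config(env_kinds = env_kinds, conditions = "both"),
                     policy = "greedy", seed = seed + 1L, lesion = lesion)
    sp <- strategy_proportions(both$log)
    forced$trials |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean_steps = mean(.data$steps_to_goal),
                       .groups = "drop") |>
      dplyr::mutate(p_direction_both = sp$overall)
  }
  out <- lapply(names(lesions), function(nm) {
    res <- run(if (length(lesions[[nm]])) lesions[[nm]] else NULL)
    res$lesion <- nm
    res
  })
  out <- dplyr::bind_rows(out)
  intact <- out[out$lesion == "intact", c("condition", "mean_steps")]
  names(intact)[2] <- "intact_steps"
  out <- dplyr::left_join(out, intact, by = "condition")
  out$excess_steps <- out$mean_steps - out$intact_steps
  out
}

# Closed-form ridge regression with unpenalised intercept:
# minimise ||y - Xw - b||^2 + alpha ||w||^2.
.ridge_fit <- function(X, y, alpha = 0.5) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  w <- solve(crossprod(Xc) + diag(alpha, ncol(X)), crossprod(Xc, yc))
  list(w = w, b = ym - drop(xm %*% w))
}

.train_test_split <- function(n, test_frac = 0.2) {
  test <- sample.int(n, round(test_frac * n))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Decode a continuous location from a unit set
#'
#' Ridge regressions (penalty 0.5) predict the x- and y-coordinates of the
#' current or goal location from the cell states of `unit_set`; fit on a
#' seeded 80% split, scored as the mean Euclidean distance between predicted
#' and true locations on the held-out 20%.
#'
#' @param dataset An [activation_dataset()].
#' @param unit_set Integer unit indices.
#' @param target `"current"` or `"goal"`.
#' @param alpha Ridge penalty. @param seed Split seed.
#' @return List `error` (mean held-out Euclidean error, grid units) and
#'   `n_test`.
#' @export
decode_continuous <- function(dataset, unit_set, target = c("current", "goal"),
                              alpha = 0.5, seed = 1L, test_frac = 0.2) {
  target <- match.arg(target)
  ann <- dataset$annotations
  X <- dataset$activations[, unit_set, drop = FALSE]
  if (nrow(X) < 100L) stop("need at least 100 timesteps")
  Y <- if (target == "current") cbind(x = ann$col, y = ann$row)
       else cbind(x = ann$goal_col, y = ann$goal_row)
  if (nrow(unique(Y)) < 2L) stop("fewer than 2 distinct target locations")
  set.seed(as.integer(seed))
  sp <- .train_test_split(nrow(X), test_frac)
  pred <- sapply(1:2, function(j) {
    fit <- .ridge_fit(X[sp$train, , drop = FALSE], Y[sp$train, j], alpha)
    drop(X[sp$test, , drop = FALSE] %*% fit$w) + fit$b
  })
  err <- sqrt(rowSums((pred - Y[sp$test, ])^2))
  list(error = mean(err), n_test = length(sp$test))
}

#' Decode a binary adjacency variable from a unit set
#'
#' Logistic regression on the unit set predicting landmark or goal
#' adjacency. The majority class is undersampled (seeded) to balance the
#' classes before the 80/20 split; the score is the held-out
#' misclassification proportion.
#'
#' @inheritParams decode_continuous
#' @param target `"landmark"` or `"goal"`.
#' @return List `error` (held-out misclassification rate), `n_test`, and
#'   `n_per_class` after undersampling.
#' @export
decode_binary <- function(dataset, unit_set, target = c("landmark", "goal"),
                          seed = 1L, test_frac = 0.2) {
  target <- match.arg(target)
  ann <- dataset$annotations
  y <- if (target == "landmark") ann$landmark_adjacent else ann$goal_adjacent
  if (length(unique(y)) < 2L) stop("a class is absent")
  X <- dataset$activations[, unit_set, drop = FALSE]
  set.seed(as.integer(seed))
  pos <- which(y); neg <- which(!y)
  n_min <- min(length(pos), length(neg))
  keep <- c(sample(pos, n_min), sample(neg, n_min))
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  sp <- .train_test_split(length(y), test_frac)
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df[sp$train, ], family = stats::binomial()))
  p <- suppressWarnings(
    stats::predict(fit, newdata = df[sp$test, ], type = "response"))
  list(error = mean((p > 0.5) != y[sp$test]), n_test = length(sp$test),
       n_per_class = n_min)
}

#' Representational-geometry PCA over a unit set
#'
#' Mean-centred PCA of the cell-state activations of `unit_set`; the first
#' three component scores are averaged per grid location under each level
#' of a condition split (before/after the first landmark encounter, or
#' landmark vs non-landmark location).
#'
#' @param dataset An [activation_dataset()]. @param unit_set Unit indices.
#' @param condition_split Annotation column to split on
#'   (`"post_landmark"` or `"landmark_adjacent"`).
#' @return List `pca` (the `prcomp` fit), `centroids` (tibble: row, col,
#'   condition, PC1..PC3), `variance_explained`.
#' @export
representational_pca <- function(dataset, unit_set,
                                 condition_split = "post_landmark") {
  if (length(unit_set) < 3L) stop("need at least 3 units")
  X <- dataset$activations[, unit_set, drop = FALSE]
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ann <- dataset$annotations
  sc <- pca$x[, seq_len(min(3L, ncol(pca$x))), drop = FALSE]
  df <- tibble::tibble(row = ann$row, col = ann$col,
                       condition = ann[[condition_split]])
  df <- cbind(df, as.data.frame(sc))
  centroids <- df |>
    dplyr::group_by(.data$row, .data$col, .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"), mean),
                     .groups = "drop")
  list(pca = pca, centroids = centroids,
       variance_explained = pca$sdev^2 / sum(pca$sdev^2))
}
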