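# Landmark-sampling analytics: accessibility (mean distance from every state
# to its nearest landmark), centrality (mean distance from landmarks to the
# grid centre), probe-error summaries, and the subjects x locations sampling
# PCA. Distances are Manhattan grid steps: that is the only metric under
# which the uniform-placement chance level equals the grid's printed value
# of 4 (a Euclidean variant is available behind `metric`).

.dist_fun <- function(metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "manhattan") function(dr, dc) abs(dr) + abs(dc)
  else function(dr, dc) sqrt(dr^2 + dc^2)
}

#' Mean distance from every state to its nearest landmark
#'
#' Averaged over all 64 interior cells; lower values mean the landmark set
#' is more accessible from everywhere. Landmark multiplicity is ignored
#' (each unique cell counts once) unless `weights` gives sampling counts.
#'
#' @param landmark_cells n x 2 matrix of (row, col) landmark cells.
#' @param metric `"manhattan"` (grid steps, default) or `"euclidean"`.
#' @export
mean_nearest_landmark_distance <- function(landmark_cells,
                                           metric = "manhattan") {
  if (is.null(dim(landmark_cells))) landmark_cells <- matrix(landmark_cells, 1)
  if (nrow(landmark_cells) == 0L) stop("empty landmark set")
  landmark_cells <- unique(landmark_cells[, 1:2, drop = FALSE])
  d <- .dist_fun(metric)
  cells <- expand.grid(row = 0:7, col = 0:7)
  nearest <- vapply(seq_len(nrow(cells)), function(i)
    min(d(landmark_cells[, 1] - cells$row[i],
          landmark_cells[, 2] - cells$col[i])), numeric(1))
  mean(nearest)
}

#' Mean distance from landmarks to the grid centre
#'
#' Centre of the 8x8 interior is (3.5, 3.5) in 0-based coordinates. Unique
#' landmark cells count once by default; set `count_weighted = TRUE` to
#' weight by sampling multiplicity (rows repeated in `landmark_cells`).
#'
#' @inheritParams mean_nearest_landmark_distance
#' @export
mean_center_distance <- function(landmark_cells, metric = "manhattan",
                                 count_weighted = FALSE) {
  if (is.null(dim(landmark_cells))) landmark_cells <- matrix(landmark_cells, 1)
  if (nrow(landmark_cells) == 0L) stop("empty landmark set")
  if (!count_weighted)
    landmark_cells <- unique(landmark_cells[, 1:2, drop = FALSE])
  d <- .dist_fun(metric)
  mean(d(landmark_cells[, 1] - 3.5, landmark_cells[, 2] - 3.5))
}

#' Chance level of the centre-distance metric
#'
#' Exact enumeration of the mean centre distance over every interior cell of
#' an n x n grid; 4 for the default 8x8 interior.
#' @param n Interior side length. @inheritParams mean_nearest_landmark_distance
#' @export
chance_center_distance <- function(n = 8L, metric = "manhattan") {
  ctr <- (n - 1) / 2
  cells <- expand.grid(row = 0:(n - 1), col = 0:(n - 1))
  d <- .dist_fun(metric)
  mean(d(cells$row - ctr, cells$col - ctr))
}

#' Mean probe-placement error
#'
#' Mean Manhattan distance between probe responses and true locations.
#' @param probe_records Tibble/data.frame with `resp_row`, `resp_col`,
#'   `true_row`, `true_col`.
#' @export
probe_error_summary <- function(probe_records) {
  if (nrow(probe_records) == 0L) stop("no probe records")
  mean(abs(probe_records$resp_row - probe_records$true_row) +
       abs(probe_records$resp_col - probe_records$true_col))
}

#' PCA of the subjects x locations sampling matrix
#'
#' Column-mean-centred (unscaled) PCA of per-subject sampling counts over
#' the 64 interior locations; loadings reshape to 8x8 row-major for display.
#'
#' @param counts Subjects x 64 count matrix (columns in row-major cell
#'   order: cell (r, c) at column r\*8 + c + 1).
#' @param n_components Components to return reshaped loadings for.
#' @return List `pca`, `scores` (subjects x components), `loadings_grid`
#'   (list of 8x8 matrices), `variance_explained`.
#' @export
sampling_pca <- function(counts, n_components = 3L) {
  if (nrow(counts) < 3L) stop("need at least 3 subjects")
  if (all(apply(counts, 2, stats::var) == 0))
    stop("degenerate sampling matrix: no between-subject variance")
  pca <- stats::prcomp(counts, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$rotation))
  loadings_grid <- lapply(seq_len(k), function(j)
    t(matrix(pca$rotation[, j], nrow = 8, ncol = 8)))  # row-major reshape
  list(pca = pca, scores = pca$x[, seq_len(k), drop = FALSE],
       loadings_grid = loadings_grid,
       variance_explained = pca$sdev^2 / sum(pca$sdev^2))
}
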