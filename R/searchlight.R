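#' Integer offsets of a voxel sphere
#'
#' All integer lattice offsets within Euclidean distance `radius` (voxel
#' units) of the origin, compared on squared integer distances so the
#' boundary is exact. Radius 3 yields 123 offsets.
#'
#' @param radius Sphere radius in voxel units (default 3).
#' @return Integer matrix, offsets x 3.
#' @export
sphere_offsets <- function(radius = 3) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Voxel membership of one searchlight sphere
#'
#' @param center Integer vector (i, j, k), 1-based voxel coordinate; must
#'   lie inside the mask.
#' @param mask Logical 3-D array.
#' @param radius Sphere radius in voxel units (default 3; edge spheres keep
#'   whatever members fall in-mask).
#' @return List with `center` and `members`: ascending flat indices of
#'   in-mask voxels within the sphere (always includes the center).
#' @export
sphere_indices <- function(center, mask, radius = 3) {
  dims <- dim(mask)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > dims))
    stop("center outside the volume")
  if (!mask[center[1], center[2], center[3]])
    stop("center voxel is outside the mask")
  pts <- sweep(sphere_offsets(radius), 2, center, "+")
  ok <- pts[, 1] >= 1L & pts[, 1] <= dims[1] &
        pts[, 2] >= 1L & pts[, 2] <= dims[2] &
        pts[, 3] >= 1L & pts[, 3] <= dims[3]
  pts <- pts[ok, , drop = FALSE]
  flat <- as.integer(pts[, 1] + (pts[, 2] - 1L) * dims[1] +
                       (pts[, 3] - 1L) * dims[1] * dims[2])
  list(center = center, members = sort(flat[mask[flat]]))
}

#' Run a per-sphere statistic over every in-mask voxel
#'
#' Map-reduce searchlight driver: for each in-mask center voxel, the
#' statistic is evaluated on the dataset's patterns restricted to the
#' sphere's in-mask members and the scalar result is written to the center
#' voxel of the output map. A failing statistic yields NaN at that center
#' (with one summary warning), never a crash of the whole map. Results are
#' independent of traversal order provided the statistic is pure.
#'
#' @param dataset A [pattern_dataset].
#' @param statistic Function of one argument, an array
#'   `sphere voxels x runs x conditions` (3rd dimension named by condition),
#'   returning a single number.
#' @param radius Sphere radius in voxel units (default 3).
#' @param min_voxels Minimum sphere size; smaller edge spheres yield NaN
#'   (default 1, i.e., no filtering).
#' @param statistic_name Label stored in the output map.
#' @return An object of class `"stat_map"`: list with `grid`, `values`
#'   (3-D array, NaN outside the mask), `statistic_name`.
#' @export
run_searchlight <- function(dataset, statistic, radius = 3, min_voxels = 1,
                            statistic_name = "statistic") {
  stopifnot(inherits(dataset, "pattern_dataset"))
  dims <- dataset$grid$dims
  values <- array(NaN, dims)
  offs <- sphere_offsets(radius)
  mask <- dataset$mask
  mask_index <- dataset$mask_index
  pos_of <- integer(prod(dims))
  pos_of[mask_index] <- seq_along(mask_index)
  centers <- arrayInd(mask_index, dims)
  n_fail <- 0L
  for (i in seq_along(mask_index)) {
    pts <- sweep(offs, 2, centers[i, ], "+")
    ok <- pts[, 1] >= 1L & pts[, 1] <= dims[1] &
          pts[, 2] >= 1L & pts[, 2] <= dims[2] &
          pts[, 3] >= 1L & pts[, 3] <= dims[3]
    pts <- pts[ok, , drop = FALSE]
    flat <- pts[, 1] + (pts[, 2] - 1L) * dims[1] +
      (pts[, 3] - 1L) * dims[1] * dims[2]
    flat <- flat[mask[flat]]
    if (length(flat) < min_voxels) next
    sub <- dataset$patterns[pos_of[sort(flat)], , , drop = FALSE]
    val <- tryCatch(statistic(sub), error = function(e) {
      n_fail <<- n_fail + 1L
      NaN
    })
    values[mask_index[i]] <- val
  }
  if (n_fail > 0L)
    warning(sprintf("statistic failed at %d sphere center(s); NaN stored",
                    n_fail))
  structure(list(grid = dataset$grid, values = values,
                 statistic_name = statistic_name),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("stat_map '%s': %d finite voxels, range [%.3g, %.3g]\n",
              x$statistic_name, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Searchlight statistic: Kendall tau-a model fit
#'
#' Returns a per-sphere statistic evaluating the fit between the sphere's
#' neural RSM and a binary model RSM via [kendall_tau_a()].
#'
#' @param model A `model_rsm` built for the dataset's run count.
#' @return A function usable as the `statistic` of [run_searchlight()].
#' @export
searchlight_rsa_statistic <- function(model) {
  conds <- unique(model$items$condition)
  force(model)
  function(pats) {
    n_runs <- dim(pats)[2]
    items <- rsm_items(conds, n_runs)
    mat <- vapply(seq_len(nrow(items)),
                  function(i) pats[, items$run[i], items$condition[i]],
                  numeric(dim(pats)[1]))
    kendall_tau_a(rsm_from_matrix(mat, items), model)
  }
}

#' Searchlight statistic: classification accuracy
#'
#' Returns a per-sphere statistic computing leave-one-run-out SVM accuracy
#' between two contrasts, with sphere-mean removal applied by default.
#'
#' @param contrast_a,contrast_b [contrast_spec()] objects.
#' @param cost SVM cost parameter (default 1).
#' @param center Remove the sphere mean from each pattern first
#'   (default `TRUE`).
#' @return A function usable as the `statistic` of [run_searchlight()].
#' @export
searchlight_mvpa_statistic <- function(contrast_a, contrast_b, cost = 1,
                                       center = TRUE) {
  force(contrast_a); force(contrast_b)
  contrast_of <- function(pats, spec) {
    plus <- matrix(pats[, , spec$plus], ncol = dim(pats)[2])
    if (identical(spec$minus, "rest")) plus
    else plus - matrix(pats[, , spec$minus], ncol = dim(pats)[2])
  }
  function(pats) {
    loro_cv_accuracy(contrast_of(pats, contrast_a),
                     contrast_of(pats, contrast_b),
                     cost = cost, center = center)$mean_accuracy
  }
}
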