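# Neighbour offset table for 6/18/26-connectivity.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1,
                 "18" = d >= 1 & rowSums(g != 0) <= 2,
                 "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary volume
#'
#' Breadth-first labelling of TRUE voxels under face (6), edge (18) or
#' corner (26) connectivity.
#'
#' @param binary Logical (or 0/1) 3-D array.
#' @param connectivity 6 (default), 18 or 26.
#' @return List with `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per component, component order = discovery order).
#' @export
label_components <- function(binary, connectivity = 6) {
  dims <- dim(binary)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dims)
  fg <- which(binary != 0)
  sizes <- integer(0)
  current <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    current <- current + 1L
    labels[start] <- current
    queue <- integer(length(fg))
    queue[1L] <- start
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      ijk <- arrayInd(v, dims)[1, ]
      nb <- sweep(offs, 2, ijk, "+")
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
            nb[, 2] >= 1L & nb[, 2] <= dims[2] &
            nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      flat <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      flat <- flat[binary[flat] != 0 & labels[flat] == 0L]
      if (length(flat)) {
        labels[flat] <- current
        queue[(tail + 1L):(tail + length(flat))] <- flat
        tail <- tail + length(flat)
      }
    }
    sizes[current] <- tail
  }
  list(labels = labels, sizes = sizes)
}

# One-sample t statistics per voxel for an n x V data matrix, using the
# sign-flip-invariant sum of squares. Zero-variance voxels get t = 0 when
# their mean is also 0 and +/-Inf otherwise.
voxelwise_t <- function(x, signs = rep(1, nrow(x)), ss = colSums(x^2)) {
  n <- nrow(x)
  m <- colMeans(x * signs)
  v <- pmax((ss - n * m^2) / (n - 1), 0)
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  t
}

#' Sign-flip permutation test with cluster-extent FWE correction
#'
#' Second-level inference over subject statistic maps. Subject maps are
#' (optionally) smoothed, centred at the null value (0 for tau maps, 0.5
#' for accuracy maps), and a one-sample t statistic is computed per voxel.
#' The cluster-forming threshold is the parametric t quantile at `voxel_p`
#' (df = n - 1); a stricter/looser dual threshold may be applied inside a
#' supplied ROI. Suprathreshold voxels are grouped into connected clusters,
#' whose sizes are scored against the permutation distribution of the
#' maximum cluster size under random per-subject sign flips:
#' `cluster_p = (1 + #{perm max >= observed}) / (1 + n_perm)`.
#'
#' When `n_perm >= 2^n_subjects` the full set of sign assignments is
#' enumerated exactly instead (with a warning if `n_perm` exceeded it).
#'
#' @param maps List of subject `stat_map` objects or 3-D arrays on a common
#'   grid (NaN outside the analysis mask).
#' @param null_value Value subtracted from every map before testing
#'   (default 0).
#' @param n_perm Number of permutations (default 5000, minimum 100).
#' @param voxel_p Cluster-forming voxel p threshold (default 0.001).
#' @param roi Optional logical array; inside it `roi_voxel_p` is used
#'   instead (default 0.005), the conventional looser threshold for a
#'   preregistered region.
#' @param roi_voxel_p Voxel p inside `roi`.
#' @param cluster_p Cluster-level FWE threshold used for the significance
#'   flag (default 0.05).
#' @param smooth_fwhm_mm FWHM (mm) of Gaussian smoothing applied to each
#'   subject map before testing (default 4; set 0 to disable). Requires
#'   `grid` when nonzero and maps are plain arrays.
#' @param grid A [volume_grid()] (taken from the first `stat_map` if
#'   absent).
#' @param connectivity Cluster connectivity: 6 (default), 18 or 26.
#' @param seed Integer seed for the sign flips.
#' @return An object of class `"cluster_result"`: list with `clusters`
#'   (data frame: size, peak i/j/k, peak mm coordinates when a grid is
#'   known, peak t, cluster_p, significant), `thresholded_map` (logical
#'   array of suprathreshold voxels), `t_map`, `null_max_sizes`, `n_perm`.
#' @export
signflip_permutation_test <- function(maps, null_value = 0, n_perm = 5000,
                                      voxel_p = 0.001, roi = NULL,
                                      roi_voxel_p = 0.005, cluster_p = 0.05,
                                      smooth_fwhm_mm = 4, grid = NULL,
                                      connectivity = 6, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  arrays <- lapply(maps, function(m)
    if (inherits(m, "stat_map")) m$values else m)
  if (is.null(grid) && inherits(maps[[1]], "stat_map"))
    grid <- maps[[1]]$grid
  n <- length(arrays)
  if (n < 2L) stop("need >= 2 subjects")
  dims <- dim(arrays[[1]])
  for (a in arrays) if (!identical(dim(a), dims))
    stop("subject maps are on different grids")
  if (smooth_fwhm_mm > 0) {
    if (is.null(grid)) stop("'grid' required for map smoothing in mm")
    msk <- is.finite(arrays[[1]])
    for (a in arrays[-1]) msk <- msk & is.finite(a)
    arrays <- lapply(arrays, function(a) {
      a[!msk] <- 0
      smooth_volume(a, grid = grid, mask = msk, fwhm_mm = smooth_fwhm_mm)
    })
    for (i in seq_along(arrays)) arrays[[i]][!msk] <- NaN
  }
  mask <- is.finite(arrays[[1]])
  for (a in arrays[-1]) mask <- mask & is.finite(a)
  mask_index <- which(mask)
  V <- length(mask_index)
  if (V == 0L) stop("no voxel is finite in every subject map")
  x <- do.call(rbind, lapply(arrays, function(a) a[mask_index])) - null_value
  ss <- colSums(x^2)
  df <- n - 1
  tcrit <- rep(stats::qt(1 - voxel_p, df), V)
  if (!is.null(roi)) {
    in_roi <- roi[mask_index] != 0
    tcrit[in_roi] <- stats::qt(1 - roi_voxel_p, df)
  }
  cluster_sizes <- function(t_vals) {
    supra <- array(FALSE, dims)
    supra[mask_index] <- t_vals > tcrit
    label_components(supra, connectivity)
  }
  t_obs <- voxelwise_t(x, ss = ss)
  obs <- cluster_sizes(t_obs)
  exhaustive <- n_perm >= 2^n
  if (n_perm > 2^n)
    warning(sprintf("n_perm (%d) exceeds 2^%d sign assignments; %s",
                    n_perm, n, "enumerating exhaustively instead"))
  local_seed(seed)
  sign_mat <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    n_perm <- nrow(m)
    m
  } else matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
  null_max <- vapply(seq_len(n_perm), function(p) {
    tp <- voxelwise_t(x, signs = sign_mat[p, ], ss = ss)
    cs <- cluster_sizes(tp)$sizes
    if (length(cs)) max(cs) else 0L
  }, numeric(1))
  if (length(obs$sizes)) {
    peaks <- t(vapply(seq_along(obs$sizes), function(cl) {
      vox <- which(obs$labels == cl)
      tv <- array(NaN, dims)
      tv[mask_index] <- t_obs
      best <- vox[which.max(tv[vox])]
      c(best, tv[best])
    }, numeric(2)))
    pk_ijk <- arrayInd(as.integer(peaks[, 1]), dims)
    clusters <- data.frame(
      size = obs$sizes,
      peak_i = pk_ijk[, 1], peak_j = pk_ijk[, 2], peak_k = pk_ijk[, 3],
      peak_t = peaks[, 2],
      cluster_p = vapply(obs$sizes, function(s)
        (1 + sum(null_max >= s)) / (1 + n_perm), numeric(1))
    )
    if (!is.null(grid)) {
      mm <- voxel_coords_mm(grid, as.integer(peaks[, 1]))
      clusters$peak_x_mm <- mm[, 1]
      clusters$peak_y_mm <- mm[, 2]
      clusters$peak_z_mm <- mm[, 3]
    }
    clusters$significant <- clusters$cluster_p < cluster_p
    clusters <- clusters[order(-clusters$size), , drop = FALSE]
  } else {
    clusters <- data.frame(size = integer(0), peak_i = integer(0),
                           peak_j = integer(0), peak_k = integer(0),
                           peak_t = numeric(0), cluster_p = numeric(0),
                           significant = logical(0))
  }
  t_map <- array(NaN, dims)
  t_map[mask_index] <- t_obs
  structure(list(clusters = clusters,
                 thresholded_map = obs$labels > 0,
                 labels = obs$labels,
                 t_map = t_map, null_max_sizes = null_max,
                 n_perm = n_perm, exhaustive = exhaustive),
            class = "cluster_result")
}

#' N-way overlap (conjunction) of binary maps
#'
#' Voxelwise AND of binary volumes, with connected components smaller than
#' `min_cluster_size` removed. Associative and commutative in its inputs.
#'
#' @param binary_maps Nonempty list of logical/0-1 arrays on a common grid.
#' @param min_cluster_size Minimum surviving component size (default 1).
#' @param connectivity Component connectivity (default 6).
#' @return List with `map` (logical array) and `cluster_sizes` (sizes of
#'   the surviving components).
#' @export
overlap_map <- function(binary_maps, min_cluster_size = 1, connectivity = 6) {
  if (length(binary_maps) == 0L) stop("empty input list")
  dims <- dim(binary_maps[[1]])
  out <- array(TRUE, dims)
  for (m in binary_maps) {
    if (!identical(dim(m), dims)) stop("maps are on different grids")
    out <- out & (m != 0)
  }
  lab <- label_components(out, connectivity)
  keep <- which(lab$sizes >= min_cluster_size)
  list(map = array(lab$labels %in% keep, dims),
       cluster_sizes = lab$sizes[keep])
}
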