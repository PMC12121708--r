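#' Inverse-Euclidean-distance spatial weights
#'
#' Pairwise weights `w_ij = 1 / d_ij` (mm) between ROI voxels, zero on the
#' diagonal, optionally truncated beyond a distance cutoff to keep the
#' matrix sparse in spirit for large ROIs (the full matrix is O(V^2)).
#'
#' @param coords_mm Numeric matrix, voxels x 3: world coordinates (mm); see
#'   [voxel_coords_mm()].
#' @param cutoff_mm Optional distance beyond which weights are set to 0
#'   (default `NULL`, no cutoff; a 12 mm cutoff is a practical choice for
#'   ROIs above ~2000 voxels).
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
morans_weights <- function(coords_mm, cutoff_mm = NULL) {
  D <- as.matrix(stats::dist(coords_mm))
  W <- matrix(0, nrow(D), ncol(D))
  nz <- D > 0
  W[nz] <- 1 / D[nz]
  if (!is.null(cutoff_mm)) W[D > cutoff_mm] <- 0
  W
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with `W = sum_ij w_ij`. Under spatial independence
#' `E[I] = -1/(N-1)`; smoother maps score higher. Invariant to affine
#' transforms of the values.
#'
#' @param values Numeric vector of per-voxel values (length N >= 2, not
#'   constant).
#' @param weights Weight matrix from [morans_weights()].
#' @return Moran's I.
#' @export
morans_i <- function(values, weights) {
  N <- length(values)
  if (N < 2L) stop("need >= 2 voxels")
  if (!identical(dim(weights), c(N, N)))
    stop("weight matrix does not match the number of voxels")
  xc <- values - mean(values)
  denom <- sum(xc^2)
  if (denom == 0) stop("constant input: Moran's I is undefined")
  (N / sum(weights)) * as.numeric(xc %*% weights %*% xc) / denom
}

#' Calibrate the post-shuffle smoothing kernel by Moran's I
#'
#' Voxel shuffling destroys the spatial autocorrelation of a map, which
#' would bias a shuffle-based permutation test. This calibration finds the
#' Gaussian kernel that restores the original smoothness: for every
#' candidate standard deviation (voxel units) it repeatedly shuffles the
#' observed ROI values, smooths them within the ROI at that sd, measures
#' Moran's I, and accumulates the sum of squared differences from the
#' observed map's I. The sd with the smallest SSE wins (ties go to the
#' smaller sd; an i.i.d. observed map calibrates to 0).
#'
#' @param values Observed ROI voxel values.
#' @param roi_index Flat voxel indices of the ROI.
#' @param dims Volume dimensions.
#' @param weights Moran's I weights for the ROI voxels.
#' @param sd_grid Candidate sds in voxel units (default 0 to 2 by 0.02).
#' @param n_rep Shuffle replicates per candidate sd (default 100;
#'   minimum 10). Fresh shuffles are drawn for every (sd, replicate).
#' @param seed Integer seed.
#' @return An object of class `"smoothness_calibration"`: list with
#'   `sd_grid`, `sse`, `best_sd`, `observed_i`, `n_rep`.
#' @export
calibrate_smoothing_sd <- function(values, roi_index, dims, weights,
                                   sd_grid = seq(0, 2, by = 0.02),
                                   n_rep = 100, seed = 1) {
  if (length(sd_grid) == 0L) stop("empty sd grid")
  if (n_rep < 10) stop("n_rep must be >= 10")
  obs_i <- morans_i(values, weights)
  local_seed(seed)
  sse <- vapply(sd_grid, function(sd) {
    s <- 0
    for (rep in seq_len(n_rep)) {
      xp <- sample(values)
      if (sd > 0) xp <- smooth_roi_values(xp, roi_index, dims, sd)
      s <- s + (morans_i(xp, weights) - obs_i)^2
    }
    s
  }, numeric(1))
  structure(list(sd_grid = sd_grid, sse = sse,
                 best_sd = sd_grid[which.min(sse)],
                 observed_i = obs_i, n_rep = n_rep),
            class = "smoothness_calibration")
}

#' @export
print.smoothness_calibration <- function(x, ...) {
  cat(sprintf(
    "smoothness_calibration: best sd %.2f voxels (observed I %.4f)\n",
    x$best_sd, x$observed_i))
  invisible(x)
}

#' Fast cross-run regression statistic with fixed predictors
#'
#' Precomputes the per-predictor-run least-squares operators so that the
#' cross-run regression (and optionally the seven-portion variance
#' partition) can be re-evaluated cheaply for many dependent matrices with
#' the same predictors — the workhorse of the voxel-shuffle permutation
#' null, where only the dependent contrast changes per iteration.
#'
#' @param X_list Named list of voxels x runs predictor matrices.
#' @param portions Also return the seven commonality portions (requires
#'   exactly 3 predictors; default `FALSE`).
#' @return A function mapping a voxels x runs dependent matrix `Y` to a
#'   named numeric vector: mean betas (`beta_*`), `r2`, `adj_r2`, and the
#'   portions when requested. Values equal [runpair_regression()] /
#'   [runpair_vpa()] output on the same inputs.
#' @export
runpair_statistic <- function(X_list, portions = FALSE) {
  X_list <- lapply(X_list, as.matrix)
  nm <- names(X_list)
  if (is.null(nm)) nm <- names(X_list) <- paste0("x", seq_along(X_list))
  if (portions && length(X_list) != 3L)
    stop("portions require exactly 3 predictors")
  n_runs <- ncol(X_list[[1]])
  V <- nrow(X_list[[1]])
  subsets <- if (portions) vpa_subsets(nm) else list(full = nm)
  # per (subset, predictor run): X, (X'X)^-1 X', and hat-free projector
  ops <- lapply(subsets, function(s) {
    lapply(seq_len(n_runs), function(b) {
      X <- cbind(1, vapply(X_list[s], function(m) m[, b], numeric(V)))
      qr_ <- qr(X)
      if (qr_$rank < ncol(X))
        stop("rank-deficient predictor matrix (predictors: ",
             paste(s, collapse = ", "), ")")
      R <- qr.R(qr_)
      P <- backsolve(R, t(qr.Q(qr_)))   # (p+1) x V: beta = P %*% y
      list(X = X, P = P)
    })
  })
  pairs <- runpair_grid(n_runs)
  full_name <- if (portions) "OIM" else "full"
  p_full <- length(subsets[[full_name]])
  function(Y) {
    Y <- as.matrix(Y)
    yc <- sweep(Y, 2, colMeans(Y), "-")
    tss <- colSums(yc^2)
    r2_of <- function(sub) {
      op <- ops[[sub]]
      r2 <- numeric(nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$dep_run[i]; b <- pairs$pred_run[i]
        beta <- op[[b]]$P %*% Y[, a]
        rss <- sum((Y[, a] - op[[b]]$X %*% beta)^2)
        r2[i] <- 1 - rss / tss[a]
      }
      r2
    }
    # full model: betas + r2
    op <- ops[[full_name]]
    betas <- matrix(0, nrow(pairs), p_full)
    r2f <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$dep_run[i]; b <- pairs$pred_run[i]
      beta <- op[[b]]$P %*% Y[, a]
      rss <- sum((Y[, a] - op[[b]]$X %*% beta)^2)
      betas[i, ] <- beta[-1]
      r2f[i] <- 1 - rss / tss[a]
    }
    mr2 <- mean(r2f)
    out <- c(colMeans(betas), mr2,
             mean(1 - (1 - r2f) * (V - 1) / (V - p_full - 1)))
    names(out) <- c(paste0("beta_", subsets[[full_name]]), "r2", "adj_r2")
    if (portions) {
      R <- vapply(setdiff(names(subsets), "OIM"),
                  function(s) mean(r2_of(s)), numeric(1))
      R[["OIM"]] <- mr2
      out <- c(out, c(
        unique_O = R[["OIM"]] - R[["IM"]],
        unique_I = R[["OIM"]] - R[["OM"]],
        unique_M = R[["OIM"]] - R[["OI"]],
        common_OI = R[["OM"]] + R[["IM"]] - R[["M"]] - R[["OIM"]],
        common_OM = R[["OI"]] + R[["IM"]] - R[["I"]] - R[["OIM"]],
        common_IM = R[["OI"]] + R[["OM"]] - R[["O"]] - R[["OIM"]],
        common_OIM = R[["O"]] + R[["I"]] + R[["M"]] -
          R[["OI"]] - R[["OM"]] - R[["IM"]] + R[["OIM"]]
      ))
    }
    out
  }
}

#' Smoothness-matched voxel-shuffle permutation null
#'
#' Permutation test for cross-run regression statistics that shuffles only
#' the self-condition (vs rest) pattern, so that similarity structure
#' shared through the common control condition stays intact under the
#' null. Each iteration draws one voxel permutation, applies it identically
#' to the self pattern of every run (preserving cross-run reliability),
#' smooths the shuffled patterns within the ROI at the calibrated sd (see
#' [calibrate_smoothing_sd()]; shuffling alone would destroy spatial
#' autocorrelation), recomputes the per-run self > control contrast, and
#' re-evaluates the statistic. Before smoothing, each shuffle preserves the
#' exact multiset of voxel values.
#'
#' P-values use the add-one rule `p = (1 + #{null >= observed}) /
#' (1 + n_perm)` (right tail; hypotheses about explained variance are
#' directional), so they are never 0. Failing iterations are redrawn, up
#' to 1% of `n_perm`.
#'
#' @param self_runs Voxels x runs matrix: self-condition (vs rest) pattern
#'   per run, ROI voxels only.
#' @param control_runs Voxels x runs matrix: control condition (e.g.,
#'   semantic) pattern per run; the dependent contrast is
#'   `self_runs - control_runs`.
#' @param roi_index Flat voxel indices of the ROI.
#' @param dims Volume dimensions.
#' @param smoothing_sd Calibrated Gaussian sd in voxel units (a
#'   `smoothness_calibration` or a number).
#' @param statistic Function mapping a voxels x runs dependent matrix to a
#'   named numeric vector (see [runpair_statistic()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the null is bit-reproducible given the seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `"perm_null"`: list with `observed`,
#'   `null_samples` (n_perm x statistics matrix), `p_values`, `n_perm`,
#'   `smoothing_sd`, `n_resampled`, `seed`.
#' @export
permuted_statistic_null <- function(self_runs, control_runs, roi_index, dims,
                                    smoothing_sd, statistic, n_perm = 1000,
                                    seed = 1,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(smoothing_sd, "smoothness_calibration"))
    smoothing_sd <- smoothing_sd$best_sd
  self_runs <- as.matrix(self_runs)
  control_runs <- as.matrix(control_runs)
  stopifnot(identical(dim(self_runs), dim(control_runs)),
            nrow(self_runs) == length(roi_index))
  V <- nrow(self_runs)
  obs <- statistic(self_runs - control_runs)
  local_seed(seed)
  null <- matrix(NA_real_, n_perm, length(obs),
                 dimnames = list(NULL, names(obs)))
  n_resampled <- 0L
  max_resample <- max(1L, floor(0.01 * n_perm))
  i <- 1L
  while (i <= n_perm) {
    perm <- sample.int(V)
    sp <- self_runs[perm, , drop = FALSE]
    if (smoothing_sd > 0)
      for (r in seq_len(ncol(sp)))
        sp[, r] <- smooth_roi_values(sp[, r], roi_index, dims, smoothing_sd)
    st <- tryCatch(statistic(sp - control_runs), error = function(e) NULL)
    if (is.null(st)) {
      n_resampled <- n_resampled + 1L
      if (n_resampled > max_resample)
        stop("more than 1% of permutation iterations failed")
      next
    }
    null[i, ] <- st
    i <- i + 1L
  }
  p <- if (alternative == "greater") {
    (1 + colSums(null >= rep(obs, each = n_perm))) / (1 + n_perm)
  } else {
    (1 + colSums(abs(null) >= rep(abs(obs), each = n_perm))) / (1 + n_perm)
  }
  structure(list(observed = obs, null_samples = null, p_values = p,
                 n_perm = n_perm, smoothing_sd = smoothing_sd,
                 n_resampled = n_resampled, seed = seed,
                 alternative = alternative),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("perm_null: %d permutations, smoothing sd %.2f voxels\n",
              x$n_perm, x$smoothing_sd))
  print(round(rbind(observed = x$observed, p = x$p_values), 4))
  invisible(x)
}
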