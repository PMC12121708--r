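#' Define a regular 3-D sampling grid
#'
#' A `volume_grid` records the voxel lattice on which all volumes, masks and
#' statistic maps in an analysis live: the number of voxels per axis, the
#' physical voxel size, and the world-space position of the first voxel.
#'
#' @param dims Integer vector of length 3: voxels along x, y, z.
#' @param voxel_size_mm Positive numeric vector of length 3 (mm per voxel).
#'   Default 3 mm isotropic, the usual resampled EPI resolution.
#' @param origin Numeric vector of length 3: world coordinate (mm) of the
#'   centre of voxel (1, 1, 1).
#' @return An object of class `"volume_grid"`.
#' @export
volume_grid <- function(dims, voxel_size_mm = c(3, 3, 3), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three integers, all >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must have length 3")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Convert a Gaussian kernel FWHM to a standard deviation
#'
#' FWHM = sd * sqrt(8 * ln 2); both in the same units.
#'
#' @param fwhm Full width at half maximum (any unit).
#' @return Standard deviation in the same unit.
#' @export
fwhm_to_sd <- function(fwhm) fwhm / sqrt(8 * log(2))

#' World coordinates (mm) of voxels
#'
#' @param grid A [volume_grid()].
#' @param flat_index Integer vector of flat (column-major, x fastest) voxel
#'   indices; defaults to every voxel.
#' @return A matrix with one row per voxel and columns x, y, z (mm).
#' @export
voxel_coords_mm <- function(grid, flat_index = seq_len(prod(grid$dims))) {
  ijk <- arrayInd(flat_index, grid$dims)
  sweep(sweep(ijk - 1, 2, grid$voxel_size_mm, "*"), 2, grid$origin, "+")
}

# Dense 1-D convolution matrix for a unit-mass discrete Gaussian. Kernel
# mass falling outside the volume is renormalised (each row sums to 1), so
# constant volumes are preserved; zero-padding at *mask* edges is handled by
# the caller, which zeroes out-of-mask voxels before convolving.
conv_matrix_1d <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sd))
  offs <- -radius:radius
  k <- exp(-offs^2 / (2 * sd^2))
  k <- k / sum(k)
  C <- matrix(0, n, n)
  for (m in seq_along(offs)) {
    src <- seq_len(n) + offs[m]
    ok <- src >= 1L & src <= n
    C[cbind(which(ok), src[ok])] <- C[cbind(which(ok), src[ok])] + k[m]
  }
  C / rowSums(C)
}

# Separable convolution of a 3-D array with per-axis Gaussian sds (voxels).
smooth_array_sd <- function(vol, sd_voxels) {
  d <- dim(vol)
  if (sd_voxels[1] > 0)
    vol <- array(conv_matrix_1d(d[1], sd_voxels[1]) %*% matrix(vol, d[1]), d)
  if (sd_voxels[2] > 0) {
    v <- aperm(vol, c(2, 1, 3))
    v <- array(conv_matrix_1d(d[2], sd_voxels[2]) %*% matrix(v, d[2]), d[c(2, 1, 3)])
    vol <- aperm(v, c(2, 1, 3))
  }
  if (sd_voxels[3] > 0) {
    v <- aperm(vol, c(3, 1, 2))
    v <- array(conv_matrix_1d(d[3], sd_voxels[3]) %*% matrix(v, d[3]), d[c(3, 1, 2)])
    vol <- aperm(v, c(2, 3, 1))
  }
  vol
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution of a 3-D array, with optional masking.
#' Voxels outside the mask are zeroed before convolution and re-masked
#' afterwards (zero-padded edge behaviour: smoothed values near the mask
#' boundary are attenuated toward zero rather than renormalised).
#'
#' The kernel may be given either as a physical FWHM in mm (converted per
#' axis using the grid's voxel sizes, so anisotropic voxels get per-axis
#' standard deviations, never an averaged one) or directly as a standard
#' deviation in voxel units applied to all three axes. A zero kernel returns
#' the input unchanged (up to masking).
#'
#' @param volume 3-D numeric array.
#' @param grid A [volume_grid()]; required when `fwhm_mm` is used.
#' @param mask Optional logical array of the same dimensions.
#' @param fwhm_mm Kernel FWHM in mm (scalar).
#' @param sd_voxels Kernel standard deviation in voxel units (scalar or
#'   length 3). Exactly one of `fwhm_mm` and `sd_voxels` must be given.
#' @return The smoothed array (zero outside `mask` when a mask is given).
#' @export
smooth_volume <- function(volume, grid = NULL, mask = NULL,
                          fwhm_mm = NULL, sd_voxels = NULL) {
  if (is.null(fwhm_mm) == is.null(sd_voxels))
    stop("give exactly one of 'fwhm_mm' or 'sd_voxels'")
  if (!is.null(fwhm_mm)) {
    if (fwhm_mm < 0) stop("kernel must be nonnegative")
    if (is.null(grid)) stop("'grid' is required when the kernel is in mm")
    sdv <- fwhm_to_sd(fwhm_mm) / grid$voxel_size_mm
  } else {
    if (any(sd_voxels < 0)) stop("kernel must be nonnegative")
    sdv <- rep_len(as.numeric(sd_voxels), 3L)
  }
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(volume)))
    volume[!mask] <- 0
  }
  out <- if (all(sdv == 0)) volume else smooth_array_sd(volume, sdv)
  if (!is.null(mask)) out[!mask] <- 0
  out
}

#' Smooth a vector of ROI voxel values in place
#'
#' Embeds `values` at `roi_index` in an otherwise-zero volume, applies
#' masked Gaussian smoothing restricted to the ROI, and returns the ROI
#' values. An `sd_voxels` of 0 returns the input unchanged.
#'
#' @param values Numeric vector, one value per ROI voxel.
#' @param roi_index Flat voxel indices of the ROI within the volume.
#' @param dims Volume dimensions (length 3).
#' @param sd_voxels Gaussian standard deviation in voxel units.
#' @return Numeric vector of smoothed ROI values (same order as input).
#' @export
smooth_roi_values <- function(values, roi_index, dims, sd_voxels) {
  if (length(values) != length(roi_index))
    stop("'values' and 'roi_index' lengths differ")
  if (sd_voxels == 0) return(values)
  vol <- array(0, dims)
  vol[roi_index] <- values
  mask <- array(FALSE, dims)
  mask[roi_index] <- TRUE
  out <- smooth_volume(vol, mask = mask, sd_voxels = sd_voxels)
  out[roi_index]
}
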