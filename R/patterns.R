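#' Define a condition contrast
#'
#' A contrast is the voxelwise difference between one condition's pattern
#' and a control condition's pattern within the same run. The special
#' control `"rest"` denotes the implicit zero baseline, so the contrast is
#' the condition pattern itself.
#'
#' @param name Contrast name (used in output tables).
#' @param plus Condition label entering positively.
#' @param minus Condition label entering negatively, or `"rest"`.
#' @return An object of class `"contrast_spec"`.
#' @export
contrast_spec <- function(name, plus, minus = "rest") {
  if (identical(plus, minus)) stop("'plus' and 'minus' must differ")
  structure(list(name = name, plus = plus, minus = minus),
            class = "contrast_spec")
}

#' The six standard contrasts of the seven-condition design
#'
#' @return Named list of [contrast_spec()] objects: self > semantic,
#'   other > semantic, self > other, introspection > categorization,
#'   memory > knowledge, and self > rest.
#' @export
default_contrasts <- function() {
  list(
    self_gt_semantic = contrast_spec("self_gt_semantic", "self", "semantic"),
    other_gt_semantic = contrast_spec("other_gt_semantic", "other", "semantic"),
    self_gt_other = contrast_spec("self_gt_other", "self", "other"),
    introspection_gt_categorization =
      contrast_spec("introspection_gt_categorization",
                    "introspection", "categorization"),
    memory_gt_knowledge = contrast_spec("memory_gt_knowledge",
                                        "memory", "knowledge"),
    self_gt_rest = contrast_spec("self_gt_rest", "self", "rest")
  )
}

#' Compute per-run contrast patterns
#'
#' Subtracts the control condition's pattern from the target condition's
#' pattern within each run (`minus = "rest"` returns the target patterns
#' unchanged). Run-shared nuisance components cancel exactly in the
#' difference.
#'
#' @param dataset A [pattern_dataset].
#' @param spec A [contrast_spec()].
#' @return An object of class `"contrast_patterns"`: list with `contrast`,
#'   `per_run` (matrix V x runs), `mask_index`, `grid`.
#' @export
compute_contrast <- function(dataset, spec) {
  stopifnot(inherits(dataset, "pattern_dataset"),
            inherits(spec, "contrast_spec"))
  for (lab in c(spec$plus, if (!identical(spec$minus, "rest")) spec$minus))
    if (!lab %in% dataset$condition_labels)
      stop("unknown condition label: ", lab)
  plus <- dataset$patterns[, , spec$plus, drop = FALSE][, , 1]
  plus <- matrix(plus, ncol = dataset$n_runs)
  per_run <- if (identical(spec$minus, "rest")) plus else {
    minus <- matrix(dataset$patterns[, , spec$minus, drop = FALSE][, , 1],
                    ncol = dataset$n_runs)
    plus - minus
  }
  structure(list(contrast = spec, per_run = per_run,
                 mask_index = dataset$mask_index, grid = dataset$grid),
            class = "contrast_patterns")
}

#' Define a region of interest over a dataset mask
#'
#' @param name ROI name.
#' @param indices Flat voxel indices of the ROI (must be a subset of the
#'   dataset mask when used); stored sorted ascending, the package-wide
#'   voxel ordering convention.
#' @return An object of class `"roi_mask"`.
#' @export
roi_mask <- function(name, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L) stop("ROI is empty")
  structure(list(name = name, indices = indices), class = "roi_mask")
}

#' Build an ROI from a binary volume
#'
#' @param name ROI name.
#' @param volume Logical/numeric 3-D array; nonzero voxels form the ROI.
#' @return A [roi_mask()].
#' @export
roi_from_volume <- function(name, volume) {
  roi_mask(name, which(volume != 0))
}

#' Restrict patterns to an ROI
#'
#' Returns the input with voxel vectors restricted to the ROI, in ascending
#' flat-index order. Works on [pattern_dataset] and `contrast_patterns`
#' objects. Every ROI voxel must lie inside the source mask.
#'
#' @param x A [pattern_dataset] or `contrast_patterns` object.
#' @param roi A [roi_mask()], or `NULL` for the identity.
#' @return Object of the same class restricted to the ROI voxels.
#' @export
extract_roi <- function(x, roi) {
  if (is.null(roi)) return(x)
  stopifnot(inherits(roi, "roi_mask"))
  pos <- match(roi$indices, x$mask_index)
  if (anyNA(pos))
    stop(sprintf("ROI '%s' contains %d voxel(s) outside the dataset mask",
                 roi$name, sum(is.na(pos))))
  if (inherits(x, "pattern_dataset")) {
    x$patterns <- x$patterns[pos, , , drop = FALSE]
    x$mask_index <- roi$indices
    msk <- array(FALSE, x$grid$dims)
    msk[roi$indices] <- TRUE
    x$mask <- msk
  } else if (inherits(x, "contrast_patterns")) {
    x$per_run <- x$per_run[pos, , drop = FALSE]
    x$mask_index <- roi$indices
  } else stop("unsupported object for ROI extraction")
  x
}
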