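# Ordered cross-run pairs (dependent run, predictor run), a != b.
runpair_grid <- function(n_runs) {
  g <- expand.grid(dep_run = seq_len(n_runs), pred_run = seq_len(n_runs))
  g <- g[g$dep_run != g$pred_run, , drop = FALSE]
  g[order(g$dep_run, g$pred_run), , drop = FALSE]
}

# OLS of y on X (no intercept column yet) via QR; returns betas, R2, adj R2.
ols_fit <- function(y, X, pred_names) {
  Xi <- cbind(`(intercept)` = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi))
    stop("rank-deficient predictor matrix (predictors: ",
         paste(pred_names, collapse = ", "), ")")
  beta <- qr.coef(qr_, y)
  res <- y - Xi %*% beta
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("dependent pattern has zero variance")
  r2 <- 1 - sum(res^2) / tss
  n <- length(y)
  p <- ncol(X)
  list(betas = beta[-1], intercept = beta[1], r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

#' Cross-run multivariate pattern regression
#'
#' For every ordered pair of distinct runs (dependent run a, predictor run
#' b), regresses the dependent contrast pattern of run a on the predictor
#' contrast patterns of run b across ROI voxels (ordinary least squares
#' with intercept), so that dependent and independent variables always come
#' from different runs and run-shared noise cannot inflate the fit. With 5
#' runs this yields 20 regressions. Betas, R-squared and adjusted R-squared
#' (n = voxels, p = predictors) are averaged across pairs.
#'
#' @param Y Numeric matrix, voxels x runs: dependent contrast per run.
#' @param X_list Named list of voxels x runs matrices: one predictor
#'   contrast per entry.
#' @return An object of class `"runpair_result"`: list with `per_pair`
#'   (data frame: dep_run, pred_run, one beta column per predictor,
#'   intercept, r2, adj_r2), `mean_betas`, `mean_r2`, `mean_adj_r2`,
#'   `n_voxels`, `predictors`.
#' @export
runpair_regression <- function(Y, X_list) {
  Y <- as.matrix(Y)
  X_list <- lapply(X_list, as.matrix)
  n_runs <- ncol(Y)
  if (n_runs < 2L) stop("need >= 2 runs")
  V <- nrow(Y)
  p <- length(X_list)
  if (V <= p + 2L) stop("need more voxels than predictors + 2")
  pred_names <- names(X_list)
  if (is.null(pred_names) || any(pred_names == ""))
    pred_names <- names(X_list) <- paste0("x", seq_len(p))
  for (m in X_list) if (!identical(dim(m), dim(Y)))
    stop("every predictor must share Y's voxels and runs")
  pairs <- runpair_grid(n_runs)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$dep_run[i]
    b <- pairs$pred_run[i]
    X <- vapply(X_list, function(m) m[, b], numeric(V))
    fit <- ols_fit(Y[, a], X, pred_names)
    rows[[i]] <- c(dep_run = a, pred_run = b, fit$betas,
                   intercept = fit$intercept, r2 = fit$r2,
                   adj_r2 = fit$adj_r2)
  }
  per_pair <- as.data.frame(do.call(rbind, rows))
  names(per_pair) <- c("dep_run", "pred_run", paste0("beta_", pred_names),
                       "intercept", "r2", "adj_r2")
  mean_betas <- colMeans(per_pair[paste0("beta_", pred_names)])
  names(mean_betas) <- pred_names
  structure(list(per_pair = per_pair, mean_betas = mean_betas,
                 mean_r2 = mean(per_pair$r2),
                 mean_adj_r2 = mean(per_pair$adj_r2),
                 n_voxels = V, predictors = pred_names),
            class = "runpair_result")
}

#' @export
print.runpair_result <- function(x, ...) {
  cat(sprintf("runpair_result: %d fits, mean R2 %.3f (adj %.3f)\n",
              nrow(x$per_pair), x$mean_r2, x$mean_adj_r2))
  print(round(x$mean_betas, 4))
  invisible(x)
}

#' Fit the cross-run pattern regression from a dataset
#'
#' Convenience wrapper: computes the dependent and predictor contrasts,
#' restricts them to the ROI, and calls [runpair_regression()]. Defaults to
#' the standard design: self > semantic regressed on other > semantic,
#' introspection > categorization and memory > knowledge.
#'
#' @param dataset A [pattern_dataset].
#' @param roi Optional [roi_mask()].
#' @param dependent Dependent [contrast_spec()].
#' @param predictors Named list of predictor [contrast_spec()]s.
#' @return A `runpair_result`.
#' @export
fit_runpair_regressions <- function(dataset, roi = NULL,
                                    dependent = default_contrasts()$self_gt_semantic,
                                    predictors = default_vpa_predictors()) {
  cm <- contrast_matrices(dataset, roi, dependent, predictors)
  runpair_regression(cm$Y, cm$X_list)
}

#' The three standard predictor contrasts
#'
#' @return Named list of [contrast_spec()]s: other > semantic (O),
#'   introspection > categorization (I), memory > knowledge (M).
#' @export
default_vpa_predictors <- function() {
  dc <- default_contrasts()
  list(other = dc$other_gt_semantic,
       introspection = dc$introspection_gt_categorization,
       memory = dc$memory_gt_knowledge)
}

contrast_matrices <- function(dataset, roi, dependent, predictors) {
  dep <- extract_roi(compute_contrast(dataset, dependent), roi)
  Xl <- lapply(predictors, function(s)
    extract_roi(compute_contrast(dataset, s), roi)$per_run)
  list(Y = dep$per_run, X_list = Xl)
}

#' Noise-ceiling pattern regression
#'
#' Identical to [fit_runpair_regressions()] except that the dependent
#' contrast's own pattern from the predictor run is appended as an
#' additional predictor (`self_replicate`). Because dependent and predictor
#' runs always differ, this estimates how much variance any model could
#' explain given run-to-run measurement noise: the ceiling's adjusted
#' R-squared bounds the full model's from above.
#'
#' @inheritParams fit_runpair_regressions
#' @return A `runpair_result` with the extra `self_replicate` predictor.
#' @export
fit_noise_ceiling <- function(dataset, roi = NULL,
                              dependent = default_contrasts()$self_gt_semantic,
                              predictors = default_vpa_predictors()) {
  cm <- contrast_matrices(dataset, roi, dependent, predictors)
  runpair_regression(cm$Y, c(cm$X_list, list(self_replicate = cm$Y)))
}

# The seven predictor subsets of a three-predictor commonality analysis.
vpa_subsets <- function(nm) {
  list(O = nm[1], I = nm[2], M = nm[3],
       OI = nm[c(1, 2)], OM = nm[c(1, 3)], IM = nm[c(2, 3)], OIM = nm)
}

#' Variance partitioning (commonality analysis) over three predictors
#'
#' Fits the seven sub-models of a three-predictor regression (each single
#' predictor, each pair, and all three) across all ordered cross-run pairs,
#' averages each sub-model's raw R-squared across pairs, and decomposes the
#' full-model R-squared into seven commonality portions by
#' inclusion-exclusion: three unique portions (one per predictor), three
#' pairwise-common portions and one portion common to all three. The seven
#' portions sum to the full-model R-squared exactly (an algebraic
#' identity). Negative portions (suppressor structure) are reported as-is,
#' never clipped.
#'
#' Portions use the additive raw-R-squared algebra; the full model's
#' adjusted R-squared is reported alongside.
#'
#' @param Y Voxels x runs dependent contrast matrix.
#' @param X_list Named list of exactly three voxels x runs predictor
#'   matrices, in order (O, I, M).
#' @return An object of class `"vpa_result"`: list with `portions` (named
#'   numeric: unique_O, unique_I, unique_M, common_OI, common_OM,
#'   common_IM, common_OIM), `full_r2`, `full_adj_r2`, `submodel_r2`
#'   (named mean R-squared of the seven sub-models), `n_pairs`.
#' @export
runpair_vpa <- function(Y, X_list) {
  if (length(X_list) != 3L)
    stop("variance partitioning requires exactly 3 predictors")
  nm <- names(X_list)
  if (is.null(nm)) nm <- names(X_list) <- c("O", "I", "M")
  subs <- vpa_subsets(nm)
  fits <- lapply(subs, function(s) runpair_regression(Y, X_list[s]))
  R <- vapply(fits, `[[`, numeric(1), "mean_r2")
  portions <- c(
    unique_O = R[["OIM"]] - R[["IM"]],
    unique_I = R[["OIM"]] - R[["OM"]],
    unique_M = R[["OIM"]] - R[["OI"]],
    common_OI = R[["OM"]] + R[["IM"]] - R[["M"]] - R[["OIM"]],
    common_OM = R[["OI"]] + R[["IM"]] - R[["I"]] - R[["OIM"]],
    common_IM = R[["OI"]] + R[["OM"]] - R[["O"]] - R[["OIM"]],
    common_OIM = R[["O"]] + R[["I"]] + R[["M"]] -
      R[["OI"]] - R[["OM"]] - R[["IM"]] + R[["OIM"]]
  )
  structure(list(portions = portions, full_r2 = R[["OIM"]],
                 full_adj_r2 = fits$OIM$mean_adj_r2,
                 submodel_r2 = R, n_pairs = nrow(fits$OIM$per_pair),
                 predictors = nm),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf("vpa_result: full R2 %.4f (adj %.4f), %d run pairs\n",
              x$full_r2, x$full_adj_r2, x$n_pairs))
  print(round(x$portions, 4))
  invisible(x)
}

#' Variance partitioning from a dataset
#'
#' @inheritParams fit_runpair_regressions
#' @return A `vpa_result` (see [runpair_vpa()]).
#' @export
variance_partition <- function(dataset, roi = NULL,
                               dependent = default_contrasts()$self_gt_semantic,
                               predictors = default_vpa_predictors()) {
  cm <- contrast_matrices(dataset, roi, dependent, predictors)
  runpair_vpa(cm$Y, cm$X_list)
}

#' Percentage of explainable variance captured by the full model
#'
#' For each subject, the ratio of the full model's mean adjusted R-squared
#' to the noise-ceiling model's, times 100; ratios are then averaged across
#' subjects. Subjects with a nonpositive ceiling are excluded with a
#' warning (the ratio is undefined there).
#'
#' @param full_adj_r2 Numeric vector: per-subject full-model mean adjusted
#'   R-squared (or a single `runpair_result`).
#' @param ceiling_adj_r2 Matching vector (or `runpair_result`) for the
#'   noise-ceiling model.
#' @return Mean percentage across usable subjects.
#' @export
explainable_variance_pct <- function(full_adj_r2, ceiling_adj_r2) {
  if (inherits(full_adj_r2, "runpair_result"))
    full_adj_r2 <- full_adj_r2$mean_adj_r2
  if (inherits(ceiling_adj_r2, "runpair_result"))
    ceiling_adj_r2 <- ceiling_adj_r2$mean_adj_r2
  if (length(full_adj_r2) != length(ceiling_adj_r2))
    stop("full and ceiling vectors must have one entry per subject")
  ok <- ceiling_adj_r2 > 0
  if (!all(ok)) {
    warning(sprintf("%d subject(s) excluded: nonpositive noise ceiling",
                    sum(!ok)))
    if (!any(ok)) stop("no subject has a positive noise ceiling")
  }
  mean(100 * full_adj_r2[ok] / ceiling_adj_r2[ok])
}
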