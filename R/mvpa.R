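#' Remove each pattern's spatial mean
#'
#' Subtracts from every pattern vector its own mean over voxels, so mean
#' activation differences between conditions cannot drive classification
#' (the standard preprocessing inside a searchlight sphere).
#'
#' @param x Numeric matrix, voxels x patterns (or a vector, one pattern).
#' @return The input with every pattern (column) mean-centred over voxels.
#' @export
remove_sphere_mean <- function(x) {
  if (is.null(dim(x))) return(x - mean(x))
  sweep(x, 2, colMeans(x), "-")
}

#' Leave-one-run-out classification accuracy
#'
#' Trains a linear support vector machine (cost `cost`, no feature scaling)
#' to discriminate class-a from class-b contrast patterns, leaving one run
#' out per fold: the classifier is trained on the remaining runs' patterns
#' (one per class per run) and tested on the held-out run's two patterns.
#' Fold accuracies are averaged arithmetically. Chance level is 50%.
#'
#' If a training fold is degenerate (e.g., identical patterns in both
#' classes, or an SVM failure), the fold falls back to predicting class a
#' for every test pattern and is flagged in `degenerate_folds`.
#'
#' @param class_a,class_b `contrast_patterns` objects or V x runs matrices
#'   over the same voxels and runs.
#' @param cost SVM cost parameter (default 1).
#' @param center If `TRUE`, apply [remove_sphere_mean()] to every pattern
#'   first (default `FALSE`; searchlight classification uses `TRUE`).
#' @return An object of class `"cv_result"`: list with `fold_accuracies`
#'   (one per run), `mean_accuracy`, `degenerate_folds`.
#' @export
loro_cv_accuracy <- function(class_a, class_b, cost = 1, center = FALSE) {
  a <- if (inherits(class_a, "contrast_patterns")) class_a$per_run else
    as.matrix(class_a)
  b <- if (inherits(class_b, "contrast_patterns")) class_b$per_run else
    as.matrix(class_b)
  if (!identical(dim(a), dim(b)))
    stop("class_a and class_b must share voxels and runs")
  n_runs <- ncol(a)
  if (n_runs < 2L) stop("need >= 2 runs for leave-one-run-out folds")
  if (center) {
    a <- remove_sphere_mean(a)
    b <- remove_sphere_mean(b)
  }
  fold_acc <- numeric(n_runs)
  degenerate <- logical(n_runs)
  y_train <- factor(rep(c("a", "b"), each = n_runs - 1L), levels = c("a", "b"))
  for (r in seq_len(n_runs)) {
    x_train <- t(cbind(a[, -r, drop = FALSE], b[, -r, drop = FALSE]))
    x_test <- t(cbind(a[, r, drop = FALSE], b[, r, drop = FALSE]))
    if (all(a[, -r, drop = FALSE] == b[, -r, drop = FALSE])) {
      # identical vectors across classes: no separating direction exists
      fold_acc[r] <- 0.5          # fallback predicts class a for both samples
      degenerate[r] <- TRUE
      next
    }
    pred <- tryCatch({
      fit <- e1071::svm(x = x_train, y = y_train, kernel = "linear",
                        cost = cost, scale = FALSE,
                        type = "C-classification")
      as.character(stats::predict(fit, x_test))
    }, error = function(e) NULL)
    if (is.null(pred)) {
      pred <- c("a", "a")          # deterministic fallback: lower label index
      degenerate[r] <- TRUE
    }
    fold_acc[r] <- mean(pred == c("a", "b"))
  }
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 degenerate_folds = which(degenerate)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean accuracy %.3f over %d folds (%s)\n",
              x$mean_accuracy, length(x$fold_accuracies),
              paste(sprintf("%.2f", x$fold_accuracies), collapse = ", ")))
  invisible(x)
}

#' Median-split relabelling of blocks into two classes
#'
#' Splits blocks at the within-participant median of a per-block score
#' (e.g., average response time) into "short" (score <= median; ties go to
#' short, a fixed rule) and "long" classes, then averages the block
#' patterns of each class within each run, yielding two per-run class
#' pattern matrices suitable for [loro_cv_accuracy()].
#'
#' @param block_patterns Numeric matrix, voxels x blocks.
#' @param block_runs Integer vector: the run of each block.
#' @param scores Numeric vector: one score per block.
#' @return List with `short` and `long` (V x runs matrices), and
#'   `assignment` (factor per block).
#' @export
relabel_blocks <- function(block_patterns, block_runs, scores) {
  block_patterns <- as.matrix(block_patterns)
  B <- ncol(block_patterns)
  if (length(scores) != B || length(block_runs) != B)
    stop("one score and one run index per block required")
  if (length(unique(scores)) == 1L)
    stop("all block scores are equal; no median split exists")
  cls <- factor(ifelse(scores <= stats::median(scores), "short", "long"),
                levels = c("short", "long"))
  runs <- sort(unique(block_runs))
  agg <- function(class_name) {
    vapply(runs, function(r) {
      sel <- block_runs == r & cls == class_name
      if (!any(sel))
        stop(sprintf("run %d has no '%s' blocks after the median split",
                     r, class_name))
      rowMeans(block_patterns[, sel, drop = FALSE])
    }, numeric(nrow(block_patterns)))
  }
  list(short = agg("short"), long = agg("long"), assignment = cls)
}
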