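#' Item ordering for representational similarity matrices
#'
#' Items are (condition, run) cells ordered condition-major: conditions in
#' their declared label order, runs ascending within each condition. Model
#' and neural RSMs built with the same labels therefore always align.
#'
#' @param condition_labels Condition labels in declared order.
#' @param n_runs Number of runs.
#' @return Data frame with columns `condition`, `run`, and `key`
#'   (`"condition.run"`).
#' @export
rsm_items <- function(condition_labels, n_runs) {
  it <- data.frame(
    condition = rep(condition_labels, each = n_runs),
    run = rep(seq_len(n_runs), times = length(condition_labels)),
    stringsAsFactors = FALSE
  )
  it$key <- paste(it$condition, it$run, sep = ".")
  it
}

# Pearson correlation RSM from a V x items matrix; errors on degenerate
# columns rather than emitting silent NaNs.
rsm_from_matrix <- function(mat, items) {
  if (nrow(mat) < 2L) stop("need >= 2 voxels to correlate patterns")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance pattern for item(s): ",
         paste(items$key[sds == 0], collapse = ", "))
  vals <- stats::cor(mat)
  dimnames(vals) <- list(items$key, items$key)
  structure(list(items = items, values = vals), class = "neural_rsm")
}

#' Build a neural representational similarity matrix
#'
#' Computes the Pearson correlation between the voxel patterns of every
#' pair of (condition, run) items, optionally within an ROI and over a
#' subset of conditions.
#'
#' @param dataset A [pattern_dataset].
#' @param roi Optional [roi_mask()].
#' @param conditions Conditions to include (default: all, in dataset order).
#' @return An object of class `"neural_rsm"`: list with `items` (see
#'   [rsm_items()]) and `values`, a symmetric correlation matrix with unit
#'   diagonal.
#' @export
build_neural_rsm <- function(dataset, roi = NULL, conditions = NULL) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  dataset <- extract_roi(dataset, roi)
  if (is.null(conditions)) conditions <- dataset$condition_labels
  if (!all(conditions %in% dataset$condition_labels))
    stop("unknown condition label(s)")
  items <- rsm_items(conditions, dataset$n_runs)
  mat <- vapply(seq_len(nrow(items)),
                function(i) dataset$patterns[, items$run[i], items$condition[i]],
                numeric(dim(dataset$patterns)[1]))
  rsm_from_matrix(mat, items)
}

#' Build a binary model RSM with its validity mask
#'
#' Constructs one of the three similarity hypotheses relating the self
#' condition to a partner condition. Each model keeps only the conditions
#' relevant to its hypothesis (all pattern similarities touching the
#' remaining, irrelevant conditions are excluded by omission):
#' \describe{
#'   \item{`self_other`}{self, other, semantic}
#'   \item{`self_introspection`}{self, semantic, introspection,
#'     categorization}
#'   \item{`self_memory`}{self, semantic, memory, knowledge}
#' }
#' Model values are 1 (similar) exactly on cross-run (self, partner) pairs
#' and 0 (dissimilar) on every other valid cell. The validity mask excludes
#' the diagonal, all same-run pairs (within-run correlations are inflated by
#' run-shared physiological noise) and all same-condition pairs.
#'
#' @param model One of `"self_other"`, `"self_introspection"`,
#'   `"self_memory"`.
#' @param n_runs Number of runs.
#' @param condition_labels Labels available in the design; must contain the
#'   conditions the model needs (rename via this argument for non-default
#'   designs).
#' @return An object of class `"model_rsm"`: list with `items`,
#'   `model_values` (binary matrix), `valid` (logical matrix), `model`,
#'   `partner`.
#' @export
build_model_rsm <- function(model = c("self_other", "self_introspection",
                                      "self_memory"),
                            n_runs,
                            condition_labels = default_conditions()) {
  model <- match.arg(model)
  sets <- list(
    self_other = list(partner = "other",
                      include = c("self", "other", "semantic")),
    self_introspection = list(partner = "introspection",
                              include = c("self", "semantic",
                                          "introspection", "categorization")),
    self_memory = list(partner = "memory",
                       include = c("self", "semantic", "memory", "knowledge"))
  )
  s <- sets[[model]]
  missing <- setdiff(s$include, condition_labels)
  if (length(missing))
    stop("design lacks condition(s) required by the model: ",
         paste(missing, collapse = ", "))
  include <- condition_labels[condition_labels %in% s$include]
  items <- rsm_items(include, n_runs)
  n <- nrow(items)
  same_run <- outer(items$run, items$run, "==")
  same_cond <- outer(items$condition, items$condition, "==")
  valid <- !same_run & !same_cond
  is_self <- items$condition == "self"
  is_partner <- items$condition == s$partner
  mv <- (outer(is_self, is_partner) | outer(is_partner, is_self)) * 1
  mv[!valid] <- 0
  dimnames(mv) <- dimnames(valid) <- list(items$key, items$key)
  structure(list(items = items, model_values = mv, valid = valid,
                 model = model, partner = s$partner),
            class = "model_rsm")
}

# tau-a by exhaustive pair enumeration over <= ~500 values: ties count 0 in
# the numerator but keep full weight in the all-pairs denominator.
tau_a_pairs <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  sum(sx[ut] * sy[ut]) / (n * (n - 1) / 2)
}

#' Kendall's tau-a between a neural and a model RSM
#'
#' Rank agreement between neural correlations and model similarity values
#' over the model's valid cells (upper triangle), using the all-pairs
#' denominator: tau-a = (concordant - discordant) / (n(n-1)/2), with tied
#' pairs contributing zero to the numerator but full weight to the
#' denominator. This is the recommended statistic for comparing a
#' correlation RSM against a tied (binary) model.
#'
#' @param neural A `neural_rsm` whose items include all of the model's
#'   items.
#' @param model A `model_rsm`.
#' @return tau-a in \[-1, 1\].
#' @export
kendall_tau_a <- function(neural, model) {
  stopifnot(inherits(neural, "neural_rsm"), inherits(model, "model_rsm"))
  idx <- match(model$items$key, neural$items$key)
  if (anyNA(idx))
    stop("neural RSM lacks item(s): ",
         paste(model$items$key[is.na(idx)], collapse = ", "))
  nv <- neural$values[idx, idx, drop = FALSE]
  sel <- model$valid & upper.tri(model$valid)
  x <- nv[sel]
  y <- model$model_values[sel]
  if (length(x) < 2L)
    stop("fewer than 2 valid RSM cells (single-run designs exclude ",
         "every cross-condition cell)")
  tau_a_pairs(x, y)
}
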