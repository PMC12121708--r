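# In-memory fixtures built in code; no stored data files.

# Wrap a V x runs x conditions array as a pattern_dataset on a trivial grid
# whose mask is the first V voxels of a tall 1-voxel-thick column (keeps the
# flat-index convention honest without caring about geometry).
toy_dataset <- function(patterns, condition_labels = dimnames(patterns)[[3]],
                        grid = NULL) {
  V <- dim(patterns)[1]
  if (is.null(grid)) grid <- volume_grid(c(V, 1, 1))
  mask <- array(FALSE, grid$dims)
  mask[seq_len(V)] <- TRUE
  if (is.null(condition_labels))
    condition_labels <- paste0("c", seq_len(dim(patterns)[3]))
  dimnames(patterns) <- list(NULL, NULL, condition_labels)
  structure(list(grid = grid, mask = mask, mask_index = which(mask),
                 patterns = patterns, condition_labels = condition_labels,
                 n_runs = dim(patterns)[2],
                 provenance = "toy fixture"),
            class = "pattern_dataset")
}

# iid-noise dataset with the seven standard conditions.
noise_dataset <- function(V, n_runs = 5, seed = 1, sd = 1) {
  set.seed(seed)
  toy_dataset(array(rnorm(V * n_runs * 7, sd = sd), c(V, n_runs, 7),
                    dimnames = list(NULL, NULL, default_conditions())))
}

# Neural RSM with hand-set values (symmetric, unit diagonal).
fake_neural_rsm <- function(items, values) {
  dimnames(values) <- list(items$key, items$key)
  structure(list(items = items, values = values), class = "neural_rsm")
}

# Independent brute-force tau-a oracle: explicit double loop over pairs.
tau_a_oracle <- function(x, y) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    num <- num + sign(x[i] - x[j]) * sign(y[i] - y[j])
  num / (n * (n - 1) / 2)
}

# Kendall tau-b (tie-corrected denominator) for the |tau_a| <= |tau_b| bound.
tau_b_stat <- function(x, y) suppressWarnings(cor(x, y, method = "kendall"))
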