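# small line-of-voxels geometry for weight-based tests
line_weights <- function(n, spacing = 1) {
  morans_weights(cbind(seq_len(n) * spacing, 0, 0))
}

test_that("Moran's I is negative for alternating neighbours and affine-invariant", {
  x <- rep(c(1, -1), 10)
  W <- line_weights(20)
  I <- morans_i(x, W)
  expect_lt(I, 0)
  expect_equal(morans_i(3 * x + 11, W), I, tolerance = 1e-12)
  expect_error(morans_i(rep(2, 20), W), "constant")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(3)
  co <- matrix(runif(40 * 3, 0, 10), 40)
  W <- morans_weights(co)
  Wn <- W / rowSums(W)   # ape row-normalises its weights internally
  for (r in 1:5) {
    x <- rnorm(40)
    expect_equal(morans_i(x, Wn),
                 ape::Moran.I(x, W, scaled = FALSE)$observed,
                 tolerance = 1e-10)
  }
})

test_that("i.i.d. maps have expectation -1/(N-1)", {
  N <- 100
  set.seed(4)
  W <- morans_weights(matrix(runif(N * 3, 0, 8), N))
  draws <- replicate(200, morans_i(rnorm(N), W))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - (-1 / (N - 1))), 3 * se + 1e-4)
})

test_that("smoothing increases spatial autocorrelation", {
  dims <- c(6, 6, 6)
  W <- morans_weights(voxel_coords_mm(volume_grid(dims), 1:216))
  set.seed(5)
  wins <- replicate(100, {
    raw <- array(rnorm(216), dims)
    sm <- smooth_volume(raw, sd_voxels = 1)
    morans_i(as.vector(sm), W) > morans_i(as.vector(raw), W)
  })
  expect_true(all(wins))
})

test_that("distance cutoffs zero long-range weights", {
  co <- cbind(c(0, 1, 5), 0, 0)
  W <- morans_weights(co, cutoff_mm = 2)
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], 0)
  expect_equal(diag(W), rep(0, 3))
  expect_true(isSymmetric(W))
})

test_that("smoothness calibration recovers degenerate and planted kernels", {
  dims <- c(7, 7, 7)
  roi <- 1:343
  g <- volume_grid(dims)
  W <- morans_weights(voxel_coords_mm(g, roi))
  set.seed(6)
  x <- rnorm(343)
  # single-candidate grid
  expect_equal(calibrate_smoothing_sd(x, roi, dims, W, sd_grid = 0,
                                      n_rep = 10, seed = 1)$best_sd, 0)
  # i.i.d. observed maps need (essentially) no smoothing: the winning sd
  # sits in the near-identity regime (discrete Gaussians with sd < ~0.5
  # voxel put under 15% relative weight on neighbours, so the SSE curve is
  # flat there and the observed map's own random I picks among them)
  for (s in 1:5) {
    cal <- calibrate_smoothing_sd(rnorm(343), roi, dims, W,
                                  sd_grid = seq(0, 2, by = 0.02),
                                  n_rep = 10, seed = s)
    expect_lt(cal$best_sd, 0.5)
  }
})

test_that("calibration recovers a planted smoothing kernel", {
  dims <- c(7, 7, 7)
  roi <- seq_len(343)
  g <- volume_grid(dims)
  W <- morans_weights(voxel_coords_mm(g, roi))
  set.seed(7)
  obs <- as.vector(smooth_volume(array(rnorm(343), dims), sd_voxels = 0.8))
  cal <- calibrate_smoothing_sd(obs, roi, dims, W,
                                sd_grid = seq(0, 2, by = 0.05),
                                n_rep = 20, seed = 2)
  # brute-force oracle on a finer grid with independent draws
  oracle_sse <- function(sd, reps = 40) {
    i_obs <- morans_i(obs, W)
    sum(replicate(reps, {
      xp <- sample(obs)
      if (sd > 0) xp <- smooth_roi_values(xp, roi, dims, sd)
      (morans_i(xp, W) - i_obs)^2
    }))
  }
  set.seed(8)
  fine <- seq(0, 2, by = 0.025)
  oracle_best <- fine[which.min(vapply(fine, oracle_sse, numeric(1)))]
  expect_lt(abs(cal$best_sd - oracle_best), 0.1 + 1e-9)
})

test_that("the shuffle permutes values and constant statistics give p = 1", {
  dims <- c(4, 4, 4)
  roi <- 1:64
  set.seed(9)
  self <- matrix(rnorm(64 * 3), 64, 3)
  ctrl <- matrix(rnorm(64 * 3), 64, 3)
  # with no smoothing, any permutation-invariant statistic is constant over
  # the null: the shuffle is a permutation, not a resampling
  stat_sum <- function(Y) c(total = sum(Y))
  pn <- permuted_statistic_null(self, ctrl, roi, dims, smoothing_sd = 0,
                                statistic = stat_sum, n_perm = 50, seed = 1)
  expect_true(all(abs(pn$null_samples - pn$observed) < 1e-9))
  const <- function(Y) c(k = 42)
  pc <- permuted_statistic_null(self, ctrl, roi, dims, 0, const,
                                n_perm = 30, seed = 2)
  expect_equal(unname(pc$p_values), 1)
})

test_that("identical seeds give bit-identical nulls and p-values never hit 0", {
  dims <- c(4, 4, 4)
  set.seed(10)
  self <- matrix(rnorm(64 * 3), 64, 3)
  ctrl <- matrix(rnorm(64 * 3), 64, 3)
  Xl <- list(O = matrix(rnorm(192), 64), I = matrix(rnorm(192), 64),
             M = matrix(rnorm(192), 64))
  stat <- runpair_statistic(Xl)
  p1 <- permuted_statistic_null(self, ctrl, 1:64, dims, 0.5, stat,
                                n_perm = 60, seed = 7)
  p2 <- permuted_statistic_null(self, ctrl, 1:64, dims, 0.5, stat,
                                n_perm = 60, seed = 7)
  expect_identical(p1$null_samples, p2$null_samples)
  expect_true(all(p1$p_values > 0))
})

test_that("the fast regression statistic equals the reference fits", {
  set.seed(11)
  Y <- matrix(rnorm(80 * 4), 80, 4)
  base <- matrix(rnorm(320), 80)
  Xl <- list(O = base + matrix(rnorm(320), 80),
             I = matrix(rnorm(320), 80),
             M = matrix(rnorm(320), 80))
  fast <- runpair_statistic(Xl, portions = TRUE)(Y)
  slow <- runpair_regression(Y, Xl)
  vp <- runpair_vpa(Y, Xl)
  expect_equal(fast[c("beta_O", "beta_I", "beta_M")],
               c(beta_O = slow$mean_betas[["O"]],
                 beta_I = slow$mean_betas[["I"]],
                 beta_M = slow$mean_betas[["M"]]), tolerance = 1e-10)
  expect_equal(fast[["adj_r2"]], slow$mean_adj_r2, tolerance = 1e-10)
  expect_equal(fast[names(vp$portions)], vp$portions, tolerance = 1e-10)
})

test_that("a planted dependence on one predictor is detected with power", {
  dims <- c(7, 7, 7)
  V <- 343
  roi <- seq_len(V)
  set.seed(12)
  hits <- replicate(10, {
    o_sig <- rnorm(V)
    Xl <- list(O = matrix(o_sig, V, 3) + matrix(rnorm(3 * V, sd = 0.3), V),
               I = matrix(rnorm(3 * V), V),
               M = matrix(rnorm(3 * V), V))
    self <- matrix(o_sig, V, 3) + matrix(rnorm(3 * V, sd = 0.5), V)
    ctrl <- matrix(rnorm(3 * V, sd = 0.5), V)
    pn <- permuted_statistic_null(self, ctrl, roi, dims, smoothing_sd = 0,
                                  statistic = runpair_statistic(Xl),
                                  n_perm = 199,
                                  seed = sample.int(1e6, 1))
    pn$p_values[["beta_O"]] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
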