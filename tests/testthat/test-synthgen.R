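test_that("block schedules satisfy their invariants across designs and seeds", {
  for (n_lab in c(2, 3, 5, 7, 8)) {
    labels <- paste0("cond", seq_len(n_lab))
    for (seed in 1:20) {
      sch <- generate_block_sequence(labels, n_runs = 3,
                                     blocks_per_condition = 2, seed = seed)
      for (r in 1:3) {
        run <- sch$entries$condition[sch$entries$run == r]
        expect_equal(as.integer(table(run)[labels]), rep(2L, n_lab))
        expect_false(any(run[-1] == run[-length(run)]))
      }
    }
  }
})

test_that("the seven-condition design yields 14 repeat-free blocks per run", {
  sch <- generate_block_sequence(default_conditions(), n_runs = 5,
                                 blocks_per_condition = 2, seed = 1)
  expect_equal(as.integer(table(sch$entries$run)), rep(14L, 5))
})

test_that("degenerate and infeasible designs are handled", {
  one <- generate_block_sequence("a", n_runs = 1, blocks_per_condition = 1,
                                 seed = 99)
  expect_equal(nrow(one$entries), 1L)
  expect_error(generate_block_sequence("a", 1, blocks_per_condition = 2),
               "infeasible")
})

test_that("schedules and datasets are bit-reproducible given a seed", {
  s1 <- generate_block_sequence(letters[1:4], 2, 2, seed = 7)
  s2 <- generate_block_sequence(letters[1:4], 2, 2, seed = 7)
  expect_identical(s1, s2)
  g <- volume_grid(c(6, 6, 6))
  spec <- planted_vpa_spec(g, seed = 11)
  expect_identical(generate_pattern_dataset(spec),
                   generate_pattern_dataset(spec))
})

test_that("noiseless generation repeats the same condition pattern across runs", {
  g <- volume_grid(c(8, 8, 8))
  L <- matrix(c(1, 0.5), 2, 1)
  spec <- generator_spec(g, array(TRUE, g$dims), n_runs = 3,
                         condition_labels = c("a", "b"), loading_matrix = L,
                         run_noise_sd = 0, obs_noise_sd = 0, seed = 2)
  ds <- generate_pattern_dataset(spec)
  expect_equal(cor(get_pattern(ds, 1, "a"), get_pattern(ds, 3, "a")), 1,
               tolerance = 1e-12)
})

test_that("run-shared noise induces the closed-form within-run correlation", {
  g <- volume_grid(c(20, 25, 10))   # V = 5000
  rs <- 0.8; os <- 0.6
  spec <- generator_spec(g, array(TRUE, g$dims), n_runs = 4,
                         condition_labels = c("a", "b"),
                         loading_matrix = matrix(0, 2, 1),
                         component_smoothness_fwhm_mm = 0,
                         run_noise_sd = rs, obs_noise_sd = os, seed = 5)
  ds <- generate_pattern_dataset(spec)
  within <- mean(sapply(1:4, function(r)
    cor(get_pattern(ds, r, "a"), get_pattern(ds, r, "b"))))
  cross <- mean(apply(expand.grid(r1 = 1:4, r2 = 1:4), 1, function(p)
    if (p[1] == p[2]) NA else
      cor(get_pattern(ds, p[1], "a"), get_pattern(ds, p[2], "b"))),
    na.rm = TRUE)
  expect_gt(within, cross)
  expect_equal(within, rs^2 / (rs^2 + os^2), tolerance = 0.05)
  expect_lt(abs(cross), 0.05)
})

test_that("orthogonal component loadings decorrelate conditions", {
  g <- volume_grid(c(25, 20, 20))   # V = 10000
  L <- rbind(a = c(1, 0), b = c(0, 1))
  spec <- generator_spec(g, array(TRUE, g$dims), n_runs = 1,
                         condition_labels = c("a", "b"), loading_matrix = L,
                         run_noise_sd = 0, obs_noise_sd = 0, seed = 8)
  ds <- generate_pattern_dataset(spec)
  expect_lt(abs(cor(get_pattern(ds, 1, "a"), get_pattern(ds, 1, "b"))), 0.1)
})

test_that("empirical pattern covariance matches the loading-implied form", {
  g <- volume_grid(c(25, 20, 20))   # V = 10000, analytic check at scale
  L <- rbind(a = c(1, 0), b = c(0.6, 0.8))
  os <- 0.5
  spec <- generator_spec(g, array(TRUE, g$dims), n_runs = 2,
                         condition_labels = c("a", "b"), loading_matrix = L,
                         component_smoothness_fwhm_mm = 0,
                         run_noise_sd = 0, obs_noise_sd = os, seed = 13)
  ds <- generate_pattern_dataset(spec)
  # cross-run cor(a, b) -> (L_a . L_b) / sqrt((|L_a|^2+os^2)(|L_b|^2+os^2))
  want <- sum(L[1, ] * L[2, ]) /
    sqrt((sum(L[1, ]^2) + os^2) * (sum(L[2, ]^2) + os^2))
  expect_equal(cor(get_pattern(ds, 1, "a"), get_pattern(ds, 2, "b")), want,
               tolerance = 0.05)
})

test_that("smoothing honours identity, mass conservation and the kernel oracle", {
  g <- volume_grid(c(9, 9, 9))
  v <- array(rnorm(prod(g$dims)), g$dims)
  expect_identical(smooth_volume(v, grid = g, sd_voxels = 0), v)
  expect_equal(smooth_volume(array(3.7, g$dims), grid = g, sd_voxels = 1.2),
               array(3.7, g$dims), tolerance = 1e-12)
  # delta spike deep in the interior (its mass never reaches the rows that
  # get boundary-renormalised): separable product of 1-D discrete Gaussians
  g19 <- volume_grid(c(19, 19, 19))
  spike <- array(0, g19$dims)
  spike[10, 10, 10] <- 1
  sm <- smooth_volume(spike, grid = g19, sd_voxels = 1)
  k1 <- numeric(19)
  k1[6:14] <- exp(-(-4:4)^2 / 2)           # 4-sd truncation
  k1 <- k1 / sum(k1)
  oracle <- outer(outer(k1, k1), k1)
  expect_lt(max(abs(sm - oracle)), 1e-6)
})

test_that("mm kernels convert per axis on anisotropic grids", {
  g <- volume_grid(c(9, 9, 9), voxel_size_mm = c(2, 3, 6))
  v <- array(rnorm(prod(g$dims)), g$dims)
  by_mm <- smooth_volume(v, grid = g, fwhm_mm = 6)
  by_sd <- smooth_volume(v, sd_voxels = fwhm_to_sd(6) / c(2, 3, 6))
  expect_equal(by_mm, by_sd, tolerance = 1e-12)
})
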