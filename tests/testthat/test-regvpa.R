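# Closed-form normal-equations OLS oracle.
ols_oracle <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  res <- y - Xi %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = as.numeric(beta), r2 = r2)
}

test_that("five runs yield exactly 20 ordered cross-run fits", {
  set.seed(1)
  Y <- matrix(rnorm(50 * 5), 50, 5)
  Xl <- list(O = matrix(rnorm(250), 50), I = matrix(rnorm(250), 50),
             M = matrix(rnorm(250), 50))
  fit <- runpair_regression(Y, Xl)
  expect_equal(nrow(fit$per_pair), 20L)
  expect_true(all(fit$per_pair$dep_run != fit$per_pair$pred_run))
})

test_that("an exactly dependent pattern recovers beta 1 and adjusted R2 1", {
  set.seed(2)
  o <- rnorm(60)
  Xl <- list(O = matrix(o, 60, 4), I = matrix(rnorm(240), 60),
             M = matrix(rnorm(240), 60))
  fit <- runpair_regression(matrix(o, 60, 4), Xl)
  expect_equal(unname(fit$mean_betas), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(fit$mean_adj_r2, 1, tolerance = 1e-10)
})

test_that("betas match a normal-equations oracle pair by pair", {
  set.seed(3)
  V <- 8
  Y <- matrix(rnorm(V * 2), V, 2)
  Xl <- list(a = matrix(rnorm(V * 2), V), b = matrix(rnorm(V * 2), V),
             c = matrix(rnorm(V * 2), V))
  fit <- runpair_regression(Y, Xl)
  for (i in seq_len(nrow(fit$per_pair))) {
    pp <- fit$per_pair[i, ]
    want <- ols_oracle(Y[, pp$dep_run],
                       sapply(Xl, function(m) m[, pp$pred_run]))
    expect_equal(as.numeric(pp[c("intercept", "beta_a", "beta_b", "beta_c")]),
                 want$beta, tolerance = 1e-10)
    expect_equal(pp$r2, want$r2, tolerance = 1e-10)
  }
})

test_that("collinear predictors raise a named error", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  expect_error(runpair_regression(matrix(rnorm(40), 20, 2),
                                  list(p1 = x, p2 = 2 * x)),
               "rank-deficient.*p1")
})

test_that("the noise ceiling bounds the full model and hits its limits", {
  g <- volume_grid(c(8, 8, 8))
  # raw-R2 nesting holds on every simulated dataset
  for (s in 1:10) {
    ds <- generate_pattern_dataset(planted_vpa_spec(g, seed = 300 + s))
    full <- fit_runpair_regressions(ds)
    ceil <- fit_noise_ceiling(ds)
    expect_gte(ceil$mean_r2, full$mean_r2)
    expect_gte(ceil$mean_adj_r2, full$mean_adj_r2 - 1e-6)
  }
  # dependent identical across runs: ceiling explains everything
  set.seed(5)
  o <- rnorm(50)
  Y <- matrix(o, 50, 3)
  Xl <- list(O = matrix(rnorm(150), 50), I = matrix(rnorm(150), 50),
             M = matrix(rnorm(150), 50))
  ceil <- runpair_regression(Y, c(Xl, list(self_replicate = Y)))
  expect_equal(ceil$mean_adj_r2, 1, tolerance = 1e-10)
  # pure-noise dependent: ceiling adjusted R2 near zero at V = 5000
  set.seed(6)
  Yn <- matrix(rnorm(5000 * 3), 5000, 3)
  Xn <- list(O = matrix(rnorm(15000), 5000), I = matrix(rnorm(15000), 5000),
             M = matrix(rnorm(15000), 5000))
  ceiln <- runpair_regression(Yn, c(Xn, list(self_replicate = Yn)))
  expect_lt(abs(ceiln$mean_adj_r2), 0.05)
})

test_that("variance partitioning fits seven sub-models that sum exactly", {
  set.seed(7)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  Xl <- list(O = matrix(rnorm(120), 40), I = matrix(rnorm(120), 40),
             M = matrix(rnorm(120), 40))
  vp <- runpair_vpa(Y, Xl)
  expect_length(vp$submodel_r2, 7L)
  expect_length(vp$portions, 7L)
  expect_lt(abs(sum(vp$portions) - vp$full_r2), 1e-10)
  # nesting of sub-model R2
  R <- vp$submodel_r2
  expect_gte(R[["OIM"]], max(R[["OI"]], R[["OM"]], R[["IM"]]) - 1e-12)
  expect_gte(min(R[["OI"]], R[["OM"]]), R[["O"]] - 1e-12)
})

test_that("portions satisfy the defining inclusion-exclusion system", {
  # independent characterisation: for every predictor subset S, the summed
  # portions of all commonality sets intersecting S equal R2(S)
  set.seed(8)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  base <- matrix(rnorm(180), 60)
  Xl <- list(O = base + matrix(rnorm(180), 60),
             I = base + matrix(rnorm(180), 60),
             M = base + matrix(rnorm(180), 60))
  vp <- runpair_vpa(Y, Xl)
  sets <- list(O = "O", I = "I", M = "M", OI = c("O", "I"),
               OM = c("O", "M"), IM = c("I", "M"), OIM = c("O", "I", "M"))
  members <- list(unique_O = "O", unique_I = "I", unique_M = "M",
                  common_OI = c("O", "I"), common_OM = c("O", "M"),
                  common_IM = c("I", "M"), common_OIM = c("O", "I", "M"))
  for (sn in names(sets)) {
    touching <- vapply(members, function(m)
      length(intersect(m, sets[[sn]])) > 0, logical(1))
    expect_equal(sum(vp$portions[touching]), vp$submodel_r2[[sn]],
                 tolerance = 1e-10)
  }
})

test_that("orthogonal and duplicated predictors place variance correctly", {
  n <- 300
  # mutually orthogonal predictors, dependent loads on O only
  set.seed(10)
  # columns of Q span a centred space: mutually orthogonal and mean-zero
  qb <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), scale = FALSE)))
  o <- qb[, 1]; i <- qb[, 2]; m <- qb[, 3]; e <- qb[, 4]
  Y <- matrix(2 * o + 0.5 * e, n, 2)
  Xl <- list(O = matrix(o, n, 2), I = matrix(i, n, 2), M = matrix(m, n, 2))
  vp <- runpair_vpa(Y, Xl)
  expect_equal(unname(vp$portions["unique_O"]), vp$full_r2, tolerance = 1e-6)
  expect_lt(max(abs(vp$portions[setdiff(names(vp$portions), "unique_O")])),
            1e-6)
  # duplicated predictors (I = M up to tiny jitter): shared portion carries it
  set.seed(9)
  im <- rnorm(n)
  Xd <- list(O = matrix(rnorm(2 * n), n),
             I = matrix(im, n, 2) + matrix(rnorm(2 * n, sd = 1e-4), n),
             M = matrix(im, n, 2) + matrix(rnorm(2 * n, sd = 1e-4), n))
  Yd <- matrix(im, n, 2)
  vpd <- runpair_vpa(Yd, Xd)
  expect_lt(abs(vpd$portions[["unique_I"]]), 0.01)
  expect_lt(abs(vpd$portions[["unique_M"]]), 0.01)
  expect_gt(vpd$portions[["common_IM"]], 0.9)
})

test_that("explainable variance is the ceiling-normalised percentage", {
  expect_equal(explainable_variance_pct(0.5, 0.5), 100)
  expect_equal(explainable_variance_pct(0.4, 0.5), 80)
  expect_equal(explainable_variance_pct(c(0.4, 0.3), c(0.5, 0.6)), 65)
  expect_warning(pct <- explainable_variance_pct(c(0.4, 0.1), c(0.5, -0.2)),
                 "nonpositive")
  expect_equal(pct, 80)
  expect_error(suppressWarnings(explainable_variance_pct(0.4, -1)),
               "no subject")
})

test_that("planted explainable-variance share is recovered at scale", {
  g <- volume_grid(c(25, 25, 16))     # V = 10000
  vals <- sapply(1:8, function(s) {
    ds <- generate_pattern_dataset(planted_vpa_spec(g, seed = 400 + s))
    c(full = fit_runpair_regressions(ds)$mean_adj_r2,
      ceil = fit_noise_ceiling(ds)$mean_adj_r2)
  })
  got <- explainable_variance_pct(vals["full", ], vals["ceil", ])
  # population covariance algebra (predictors + the self replicate, which
  # shares the semantic control's noise with O in the predictor run):
  # full R2 = 0.3188, ceiling R2 = 0.3603, share = 88.47%
  expect_equal(got, 88.47, tolerance = 3)
})
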