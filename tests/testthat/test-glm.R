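test_that("design-matrix columns are the HRF-convolved event trains", {
  times <- seq(0, 30, by = 1.5)
  ev <- data.frame(condition = "a", onset_s = 0)
  dm <- build_design_matrix(ev, times, hrf = "single")
  expect_equal(unname(dm$X[, "a"]), canonical_hrf(times, type = "single"))
  ev2 <- data.frame(condition = c("a", "b"), onset_s = c(0, 3))
  expect_error(build_design_matrix(ev2, times, conditions = c("a", "b", "c")),
               "no events")
  expect_error(build_design_matrix(data.frame(condition = "a", onset_s = 40),
                                   times), "past the last volume")
  nuis <- cbind(drift = seq_along(times))
  dm3 <- build_design_matrix(ev2, times, nuisance = nuis)
  expect_equal(colnames(dm3$X), c("a", "b", "drift"))
  expect_equal(unname(dm3$X[, "drift"]), as.numeric(seq_along(times)))
})

test_that("OLS recovers a known toy model and leaves orthogonal residuals", {
  x1 <- c(1, 0, 0, 0); x2 <- c(0, 1, 0, 0)
  X <- cbind(x1 = x1, x2 = x2)
  y <- 3 * x1 - 1 * x2
  fit <- fit_glm(matrix(y, 1), X)
  expect_equal(unname(drop(fit$betas)), c(3, -1))

  set.seed(2)
  Xr <- cbind(1, matrix(rnorm(60), 20, 3))
  yr <- matrix(rnorm(40), 2, 20)
  fr <- fit_glm(yr, Xr)
  resid <- t(yr) - Xr %*% fr$betas
  expect_lt(max(abs(crossprod(Xr, resid))), 1e-8)

  Xbad <- cbind(a = x1, b = x1)
  expect_error(fit_glm(matrix(y, 1), Xbad), "collinear.*b")
})

test_that("contrast z statistics are the normal-quantile map of t", {
  set.seed(3)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  y <- matrix(2 * X[, 1] + rnorm(50, sd = 0.5), 1)
  fit <- fit_glm(y, X, contrasts = list(a = c(1, 0)))
  t_ <- fit$t["a", 1]
  expect_equal(unname(fit$z["a", 1]),
               unname(-qnorm(pt(-abs(t_), fit$df)) * sign(t_)))
})

test_that("voxel selection enforces uniqueness and equal set sizes", {
  # 8 locations x 400 voxels; voxels 1..200 selective for location
  # ceiling(v / 25)
  set.seed(4)
  z <- matrix(rnorm(8 * 400, sd = 0.1), 8, 400)
  for (l in 1:8) z[l, ((l - 1) * 25 + 1):(l * 25)] <- 5 + rnorm(25, sd = 0.1)
  sets <- select_voxels(z, n_top = 25)
  expect_true(all(lengths(sets) == 25))
  expect_equal(sort(unname(unlist(sets))), 1:200)

  # plant voxel 300 in the top-25 of locations 1 and 2: dropped from both,
  # all sets trimmed to the new minimum (24)
  z2 <- z
  z2[1, 300] <- 10; z2[2, 300] <- 10
  sets2 <- select_voxels(z2, n_top = 25)
  expect_false(300 %in% unlist(sets2))
  expect_true(all(lengths(sets2) == 24))

  # equal sizes across random z for many seeds
  for (seed in 1:50) {
    set.seed(seed)
    zr <- matrix(rnorm(8 * 120), 8, 120)
    expect_equal(length(unique(lengths(select_voxels(zr, 10)))), 1)
  }
})

test_that("voxel selection driven by a simulated localizer recovers the retinotopic sets", {
  truth <- ground_truth(noise_sd = 0.5, voxels_per_location = 6,
                        hippocampus_voxels = 2)
  sch <- build_localizer_schedule(default_layout, seed = 12)
  loc <- simulate_localizer(truth, sch, default_spec, seed = 13)
  blocks <- sch$blocks[!sch$blocks$rest, ]
  ev <- data.frame(condition = paste0("loc", blocks$location),
                   onset_s = blocks$onset_s, duration_s = blocks$duration_s)
  times <- loc$v1$times
  dm <- build_design_matrix(ev, times, conditions = paste0("loc", 1:8),
                            hrf = "double")
  fit <- fit_glm(loc$v1$values, dm,
                 contrasts = one_vs_rest_contrasts(colnames(dm$X),
                                                   paste0("loc", 1:8)))
  sets <- select_voxels(fit$z, n_top = 6)
  expect_true(all(lengths(sets) == 6))
  for (l in 1:8)
    expect_setequal(sets[[l]], which(loc$v1$voxel_location == l))
})

test_that("control subtraction produces the documented profile arithmetic", {
  rois <- matrix(0.2, 5, 8,
                 dimnames = list(c(paste0("partial_", c("A", "B", "C", "D")),
                                   "full"), NULL))
  expect_equal(unname(control_subtract(rois, default_spec)),
               matrix(0, 4, 4))
  rois2 <- rois
  rois2["partial_A", default_spec$sequence_indices] <- c(0.5, 0.2, 0.2, 0.2)
  prof <- control_subtract(rois2, default_spec)
  expect_equal(unname(prof["A", ]), c(0.3, 0, 0, 0))
  expect_error(control_subtract(rois[1:3, ], default_spec), "missing")
})

test_that("successor/predecessor averages enumerate the right cells", {
  lag <- outer(1:4, 1:4, function(i, j) j - i)
  sp <- successor_predecessor_average(lag)
  expect_equal(sp$successor, 5 / 3)
  expect_equal(sp$predecessor, -5 / 3)
  expect_equal(unname(sp$lags), c(-3, -2, -1, 1, 2, 3))
  zero <- successor_predecessor_average(matrix(0, 4, 4))
  expect_equal(c(zero$successor, zero$predecessor), c(0, 0))
  # a per-condition global shift of all 8 ROIs is removed by control
  # subtraction, so the contrast is immune to condition-wide offsets
  set.seed(5)
  rois <- matrix(rnorm(40), 5, 8,
                 dimnames = list(c(paste0("partial_", c("A", "B", "C", "D")),
                                   "full"), NULL))
  shifts <- rnorm(5)
  prof_a <- control_subtract(rois, default_spec)
  prof_b <- control_subtract(rois + shifts, default_spec)
  expect_equal(prof_a, prof_b, tolerance = 1e-12)
})
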