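test_that("canonical HRF starts at zero, peaks near 5 s, and responds linearly", {
  expect_equal(canonical_hrf(0), 0)
  expect_equal(canonical_hrf(-2), 0)
  # dense-grid argmax oracle
  grid <- seq(0.001, 30, by = 0.001)
  expect_equal(hrf_time_to_peak("double"), grid[which.max(canonical_hrf(grid))])
  expect_equal(hrf_time_to_peak("double"), 5.0, tolerance = 0.05)
  expect_equal(max(canonical_hrf(grid)), 1)  # unit peak
  # single-gamma mode peaks at (shape - 1) / rate = 5 s
  expect_equal(hrf_time_to_peak("single"), 5.0, tolerance = 0.002)
  # linearity of the convolution in stimulus amplitude
  times <- seq(0, 40, by = 1.5)
  r1 <- hrf_response(times, c(3, 10), amplitudes = 1)
  r3 <- hrf_response(times, c(3, 10), amplitudes = 3)
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
  # boxcar response agrees with fine-grid numeric convolution
  dt <- 0.005
  fine <- seq(0, 60, by = dt)
  neural <- as.numeric(fine >= 2 & fine < 2 + 13.5)
  kern <- canonical_hrf(seq(0, 40, by = dt))
  conv <- stats::convolve(neural, rev(kern), type = "open")[seq_along(fine)] * dt
  probe <- seq(0, 40, by = 1.5)
  expect_equal(hrf_response(probe, 2, durations = 13.5),
               approx(fine, conv, xout = probe)$y, tolerance = 0.01)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  truth <- ground_truth(voxels_per_location = 2, hippocampus_voxels = 8)
  design <- build_session(default_spec, n_runs = 1, seed = 3)
  a <- simulate_subject(design, truth, default_layout, seed = 9)
  b <- simulate_subject(design, truth, default_layout, seed = 9)
  expect_identical(a$v1$values, b$v1$values)
  expect_identical(a$hippocampus$values, b$hippocampus$values)
})

test_that("noiseless null cohorts show no anticipatory activity after the GLM", {
  sim <- make_noiseless_subject(model = "H0")
  prof <- analyze_subject_v1(sim)
  off <- row(prof) != col(prof)
  expect_lt(max(abs(prof[off])), 1e-6)
  expect_equal(unname(diag(prof)), rep(1, 4), tolerance = 1e-6)
})

test_that("noiseless SR truth is recovered end to end through convolution and GLM", {
  sim <- make_noiseless_subject(gamma = 0.4)
  prof <- analyze_subject_v1(sim)
  # profile equals a * M rows through the whole round trip
  M <- successor_matrix(build_transition_matrix(), 0.4)
  expect_equal(prof, M, tolerance = 1e-6, ignore_attr = TRUE)
  f <- fit_model(prof, "SR")
  expect_equal(f$params$gamma, 0.40, tolerance = 0.005)
})

test_that("noiseless GLM betas scale linearly with stimulus amplitude", {
  design <- build_session(default_spec, n_runs = 1, seed = 21)
  t1 <- ground_truth(gamma = 0.3, noise_sd = 0, stimulus_amplitude = 1,
                     voxels_per_location = 1, hippocampus_voxels = 1)
  t2 <- ground_truth(gamma = 0.3, noise_sd = 0, stimulus_amplitude = 2,
                     voxels_per_location = 1, hippocampus_voxels = 1)
  p1 <- analyze_subject_v1(simulate_subject(design, t1, seed = 4))
  p2 <- analyze_subject_v1(simulate_subject(design, t2, seed = 4))
  expect_equal(p2, 2 * p1, tolerance = 1e-9)
})

test_that("beta noise matches the analytic OLS propagation", {
  design <- build_session(default_spec, n_runs = 1, seed = 31)
  times <- (seq_len(ceiling(design$run_duration_s[1] / 1.5)) - 1) * 1.5
  ev <- design$events
  ev$condition <- ev$trial_type
  dm <- build_design_matrix(ev[, c("condition", "onset_s")], times,
                            hrf = "double")
  sigma <- 1.5
  set.seed(8)
  noise <- matrix(rnorm(1000 * length(times), sd = sigma), 1000)
  fit <- fit_glm(noise, dm)
  analytic <- sigma * sqrt(diag(solve(crossprod(dm$X))))
  empirical <- apply(fit$betas, 1, sd)
  expect_equal(unname(empirical), unname(analytic), tolerance = 0.1)
})

test_that("hippocampal pattern mixing follows the configured tuning", {
  lay <- default_layout; spec <- default_spec
  w_t <- srmap:::hippocampus_pattern_weights(
    ground_truth(hippocampus_tuning = list(type = "temporal",
                                           intercept = 0.6, slope = -0.1)),
    spec, lay)
  idx <- spec$sequence_indices
  lags <- sapply(1:3, function(l) w_t[idx[1], idx[1 + l]])
  expect_equal(lags, 0.6 - 0.1 * (1:3))           # linear in |lag|
  w_s <- srmap:::hippocampus_pattern_weights(
    ground_truth(hippocampus_tuning = list(type = "spatial",
                                           intercept = NULL, slope = NULL)),
    spec, lay)
  # the 14.0-dva pair (A-B) is weaker than a 9.9-dva pair (A-C)
  expect_lt(w_s[idx[1], idx[2]], w_s[idx[1], idx[3]])
  w_n <- srmap:::hippocampus_pattern_weights(
    ground_truth(hippocampus_tuning = list(type = "none",
                                           intercept = NULL, slope = NULL)),
    spec, lay)
  expect_equal(w_n, diag(8))
})

test_that("cohorts counterbalance sequence starts and derive seeds deterministically", {
  c35 <- make_cohort(35, seed = 77)
  starts <- vapply(c35$subjects, function(s) s$start, integer(1))
  expect_true(all(table(starts) %in% c(4, 5)))
  c8 <- make_cohort(8, seed = 77)
  expect_setequal(vapply(c8$subjects, function(s) s$start, integer(1)), 1:8)
  c35b <- make_cohort(35, seed = 77)
  expect_identical(c35, c35b)
  expect_error(make_cohort(35), "seed")
  expect_error(make_cohort(1, seed = 1), "n_subjects")
})
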