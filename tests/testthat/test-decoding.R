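make_ts <- function(values, tr = 1.5) {
  n <- ncol(values)
  list(values = values, run = rep(1L, n), times = (seq_len(n) - 1) * tr,
       tr = tr)
}

test_that("preprocessing passes cubic trends untouched and z-scores per voxel", {
  t_ <- seq_len(40)
  cubic <- 0.001 * t_^3 - 0.05 * t_^2 + t_
  ts <- make_ts(rbind(cubic, rnorm(40)))
  out <- preprocess(ts)
  # order-3 filter is exact on a cubic, so only the z-scoring acts
  expect_equal(out$values[1, ], (cubic - mean(cubic)) / sd(cubic),
               tolerance = 1e-10)
  expect_equal(mean(out$values[2, ]), 0, tolerance = 1e-12)
  expect_equal(sd(out$values[2, ]), 1, tolerance = 1e-12)
  expect_warning(pc <- preprocess(make_ts(rbind(rep(2, 40)))), "constant")
  expect_equal(pc$values[1, ], rep(0, 40))
  expect_error(preprocess(make_ts(matrix(rnorm(4), 1))), "window")
})

test_that("z-scoring is per run", {
  v <- matrix(rnorm(60), 1)
  ts <- list(values = v, run = rep(1:2, each = 30),
             times = rep((0:29) * 1.5, 2), tr = 1.5)
  out <- preprocess(ts)
  for (r in 1:2) {
    expect_equal(mean(out$values[1, out$run == r]), 0, tolerance = 1e-12)
    expect_equal(sd(out$values[1, out$run == r]), 1, tolerance = 1e-12)
  }
})

test_that("trial windows select the stated volumes at TR 1.5", {
  ts <- make_ts(matrix(seq(0, by = 1.5, length.out = 20), 1))  # value = time
  s1 <- extract_trial_samples(ts, 0, 1L, 1, window = c(3, 13.5))
  expect_equal(s1$features[1, 1], mean(seq(3, 13.5, by = 1.5)))  # 8 volumes
  s2 <- extract_trial_samples(ts, 0, 1L, 1, window = c(3, 6))
  expect_equal(s2$features[1, 1], mean(c(3, 4.5, 6)))            # 3 volumes
  s3 <- extract_trial_samples(ts, 0, 1L, 1, window = c(0, 0))
  expect_equal(s3$features[1, 1], 0)                             # 1 volume
  expect_error(extract_trial_samples(ts, 0.2, 1L, 1, window = c(0.1, 0.9)),
               "no volume")
  expect_error(extract_trial_samples(ts, 0, 1L, 1, window = c(3, 1)),
               "window")
})

test_that("the decoder separates well-separated classes and respects L2 symmetry", {
  samp <- make_separable_samples(noise = 0.2)
  model <- train_decoder(samp)
  expect_equal(srmap:::decode_accuracy(model, samp), 1)
  ev <- evidence(model, samp)
  expect_equal(rowSums(ev), rep(1, nrow(ev)), tolerance = 1e-9)
  expect_true(all(ev >= 0 & ev <= 1))
  # duplicated feature column: identical predictions (penalty splits weights)
  dup <- samp
  dup$features <- cbind(samp$features, samp$features[, 1])
  m2 <- train_decoder(dup)
  ev2 <- evidence(m2, dup)
  expect_equal(max.col(ev2), max.col(ev))
  expect_error(train_decoder(structure(list(
    features = samp$features, labels = rep(1, nrow(samp$features))),
    class = "trial_samples")), "2 classes")
  expect_error(evidence(model, samp$features[, 1:3]), "dimension")
})

test_that("leave-one-out accuracy is perfect on separable data, chance on shuffled labels", {
  samp <- make_separable_samples(noise = 0.2, seed = 2)
  expect_equal(loo_cross_validate(samp), 1)
  # label shuffle: accuracy within the binomial 95% CI of 1/8 on 64 trials
  set.seed(3)
  shuf <- samp
  shuf$features <- matrix(rnorm(64 * 16), 64, 16)
  shuf$labels <- sample(samp$labels)
  acc <- loo_cross_validate(shuf)
  ci <- 0.125 + c(-1, 1) * 1.96 * sqrt(0.125 * 0.875 / 64)
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
})

test_that("evidence contrast cancels under uniform evidence and detects forward skew", {
  ev_unif <- matrix(0.125, 12, 8, dimnames = list(NULL, 1:8))
  shown <- rep(1:4, 3)
  ec <- evidence_contrast(ev_unif, shown, default_spec)
  expect_equal(ec$successor, 0)
  expect_equal(ec$predecessor, 0)
  # evidence concentrated on the +1 successor, remaining mass on controls:
  # the simplex forces non-successor sequence locations below baseline
  shown123 <- rep(1:3, 4)
  ev_fwd <- matrix(0, 12, 8, dimnames = list(NULL, 1:8))
  for (k in seq_len(12)) {
    ev_fwd[k, default_spec$sequence_indices[shown123[k] + 1]] <- 0.9
    ev_fwd[k, default_spec$control_indices] <- 0.025
  }
  ec2 <- evidence_contrast(ev_fwd, shown123, default_spec)
  expect_gt(ec2$successor, 0)
  expect_lt(ec2$predecessor, 0)
})

test_that("time-resolved evidence uses the 0..13.5 s volume grid", {
  truth <- ground_truth(voxels_per_location = 1, hippocampus_voxels = 16)
  design <- build_session(default_spec, n_runs = 1, seed = 6)
  sim <- simulate_subject(design, truth, seed = 61)
  loc_sched <- build_localizer_schedule(default_layout, seed = 62)
  loc <- simulate_localizer(truth, loc_sched, default_spec, seed = 63)
  dec <- analyze_subject_decoding(sim, loc, time_resolved = TRUE)
  expect_equal(dec$timecourse$offset_s, seq(0, 13.5, by = 1.5))
  expect_equal(nrow(dec$timecourse), 10)
  expect_true(all(is.finite(dec$timecourse$diff_evidence)))
})

test_that("HRF-peak fitting recovers the canonical peak, shifts equivariantly, flags flat input", {
  times <- seq(0, 13.5, by = 1.5)
  y <- canonical_hrf(times)
  f <- fit_hrf_peak(y, times)
  expect_equal(f$time_to_peak, hrf_time_to_peak("double"), tolerance = 0.05)
  f_shift <- fit_hrf_peak(canonical_hrf(times - 1), times)
  expect_equal(f_shift$time_to_peak, f$time_to_peak + 1, tolerance = 0.05)
  # invariant under positive scaling
  f_scaled <- fit_hrf_peak(5 * y, times)
  expect_equal(f_scaled$time_to_peak, f$time_to_peak, tolerance = 1e-9)
  flat <- fit_hrf_peak(rep(0, 10), times)
  expect_true(flat$no_transient)
  expect_error(fit_hrf_peak(c(1, 2), c(0, 1)), "5 time points")
})
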