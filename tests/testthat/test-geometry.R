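test_that("default layout reproduces the eight stimulus angles on the 7-dva circle", {
  lay <- build_layout(7, 8)
  expect_equal(lay$angles,
               c(22.5, 67.5, 112.5, 157.5, 202.5, 247.5, 292.5, 337.5))
  expect_equal(diff(lay$angles), rep(45, 7))
  expect_equal(sqrt(lay$x^2 + lay$y^2), rep(7, 8))

  small <- build_layout(1, 4)
  expect_equal(sqrt(small$x^2 + small$y^2), rep(1, 4))

  expect_error(build_layout(-1, 8), "radius")
  expect_error(build_layout(7, 1), "n_locations")
})

test_that("chord distances match the printed neighbour and quadrant separations", {
  lay <- build_layout()
  expect_equal(round(chord_distance(lay, 1, 2), 1), 5.4)  # 45 deg apart
  expect_equal(round(chord_distance(lay, 1, 3), 1), 9.9)  # 90 deg apart
  expect_equal(round(chord_distance(lay, 1, 5), 1), 14.0) # opposite
  expect_equal(chord_distance(lay, 3, 3), 0)
  expect_error(chord_distance(lay, 0, 1), "index")
  expect_error(chord_distance(lay, 1, 9), "index")
})

test_that("sequence construction yields 8 constrained sequences, a bijection over starts", {
  lay <- build_layout()
  specs <- enumerate_sequences(lay)
  expect_length(specs, 8)
  starts <- vapply(specs, function(s) s$sequence_indices[1], integer(1))
  expect_setequal(starts, 1:8)
  expect_equal(specs[[1]]$sequence_indices, c(1, 5, 7, 3))

  quadrant <- function(angle) floor(angle / 90) + 1
  for (s in specs) {
    idx <- s$sequence_indices
    expect_setequal(c(idx, s$control_indices), 1:8)
    # every quadrant stimulated once
    expect_setequal(quadrant(lay$angles[idx]), 1:4)
    # no two sequence locations 45 degrees apart
    d <- outer(idx, idx, function(i, j) chord_distance(lay, i, j))
    expect_gt(min(d[upper.tri(d)]), 5.5)
    # pairwise-distance multiset decouples time and space:
    # temporally adjacent A-B is spatially maximal
    expect_equal(sort(round(d[upper.tri(d)], 1)),
                 c(9.9, 9.9, 9.9, 9.9, 14.0, 14.0))
    expect_equal(round(chord_distance(lay, idx[1], idx[2]), 1), 14.0)
  }
  expect_error(enumerate_sequences(build_layout(7, 4)), "8-location")
})

test_that("temporal distance is the signed step count in sequence order", {
  spec <- default_spec
  expect_equal(temporal_distance(spec, "B", "C"), 1)
  expect_equal(temporal_distance(spec, "B", "D"), 2)
  expect_equal(temporal_distance(spec, "B", "A"), -1)
  expect_equal(temporal_distance(spec, "A", "A"), 0)
  expect_equal(temporal_distance(spec, "A", "D"), 3)
  expect_error(temporal_distance(spec, "A", "E"), "position")
})

test_that("ITI scale calibration solves the truncated-exponential mean", {
  beta <- calibrate_iti_scale(2, 10.9, 3.72)
  expect_equal(beta, 1.78, tolerance = 0.01)
  # independent check: numerically integrate the truncated density
  dens <- function(x) exp(-(x - 2) / beta)
  z <- integrate(dens, 2, 10.9)$value
  m <- integrate(function(x) x * dens(x), 2, 10.9)$value / z
  expect_equal(m, 3.72, tolerance = 1e-6)
  # untruncated limit: mean = minimum + scale
  expect_equal(calibrate_iti_scale(2, 1e6, 3.72), 1.72, tolerance = 1e-6)
  expect_error(calibrate_iti_scale(2, 10.9, 1.0), "no solution")
  expect_error(calibrate_iti_scale(2, 10.9, 8.0), "no solution")
})

test_that("ITI draws stay in bounds, reproduce, and converge to the design mean", {
  set.seed(11)
  x <- sample_itis(1e5)
  expect_true(all(x >= 2 & x <= 10.9))
  expect_equal(mean(x), 3.72, tolerance = 0.02)
  set.seed(42); a <- sample_itis(100)
  set.seed(42); b <- sample_itis(100)
  expect_identical(a, b)
})

test_that("session designs satisfy the trial-count and adjacency invariants for many seeds", {
  spec <- default_spec
  for (seed in 1:100) {
    des <- build_session(spec, n_runs = 1, seed = seed)
    ev <- des$events
    expect_equal(nrow(ev), 192)
    expect_equal(sum(ev$trial_type == "full"), 128)
    expect_equal(as.integer(table(ev$trial_type[ev$trial_type != "full"])),
                 rep(16L, 4))
    expect_equal(sum(ev$delayed), 52)
    # every partial trial flanked by full trials (so never first/last)
    part <- which(ev$trial_type != "full")
    expect_true(all(part > 1 & part < 192))
    expect_true(all(ev$trial_type[part - 1] == "full"))
    expect_true(all(ev$trial_type[part + 1] == "full"))
    expect_true(all(diff(ev$onset_s) > 0))
    expect_true(all(ev$iti_s >= 2 & ev$iti_s <= 10.9))
  }
})

test_that("sessions are bit-reproducible and carry the printed stimulus timings", {
  a <- build_session(default_spec, seed = 5)
  b <- build_session(default_spec, seed = 5)
  expect_identical(a$events, b$events)
  expect_equal(nrow(a$events), 576)
  # non-delayed full-sequence span: 4 x 100 ms + 3 x 17 ms = 451 ms
  full <- a$events$trial_type == "full" & !a$events$delayed
  expect_equal(unique(a$events$duration_s[full]), 0.451)
  delayed <- a$events$trial_type == "full" & a$events$delayed
  expect_equal(unique(a$events$duration_s[delayed]), 0.604)
  expect_equal(sum(a$events$delayed), 156)
})

test_that("localizer schedule has 64 blocks, 8 rests, and post-rest coverage of all locations", {
  lay <- build_layout()
  sch <- build_localizer_schedule(lay, seed = 3)
  blocks <- sch$blocks
  stim <- blocks[!blocks$rest, ]
  expect_equal(nrow(stim), 64)
  expect_equal(sum(blocks$rest), 8)
  expect_equal(sch$total_duration_s, 64 * 13.5 + 8 * 15)
  # each location stimulated 8 times
  expect_equal(as.integer(table(stim$location)), rep(8L, 8))
  # the 8 cycle-initial blocks cover each location exactly once
  heads <- vapply(split(stim, stim$cycle),
                  function(b) b$location[which.min(b$onset_s)], integer(1))
  expect_setequal(heads, 1:8)
  expect_identical(build_localizer_schedule(lay, seed = 3)$blocks, blocks)
})
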