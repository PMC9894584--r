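# Seeded synthetic fMRI cohorts with known generative predictive-map
# structure: retinotopic V1 subpopulations with Gaussian spatial bleed,
# hippocampal voxel patterns with configurable temporal/spatial coactivation,
# HRF-convolved at TR = 1.5 s with white Gaussian noise.

#' Ground truth for a synthetic subject or cohort
#'
#' Bundles every generator knob. Defaults are the study conditions used
#' throughout: SR generative model with gamma = 0.3, unit stimulus
#' amplitude, V1 volume-level noise SD 2, spatial bleed scale 1 dva
#' (negligible spread to 5.4-dva neighbours, emulating sharp retinotopic
#' tuning), temporal hippocampal coactivation fading linearly with sequence
#' lag.
#'
#' @param generative_model "SR", "CO" or "H0" — the model generating
#'   anticipatory activity at omitted sequence locations.
#' @param gamma SR discount factor (used when `generative_model == "SR"`).
#' @param omega CO coactivation amplitude (when `generative_model == "CO"`).
#' @param stimulus_amplitude Bottom-up response amplitude, in beta units.
#' @param noise_sd V1 white-noise SD per voxel per volume (same units).
#' @param spatial_spread Gaussian scale (dva) of V1 cross-location bleed.
#' @param hippocampus_tuning List: `type` in "temporal", "spatial", "none";
#'   `intercept`, `slope` giving the pattern-mixing weight as a function of
#'   absolute sequence lag (temporal) or chord distance in dva (spatial),
#'   clamped at 0.
#' @param hippocampus_amplitude Hippocampal response amplitude per unit
#'   pattern.
#' @param hippocampus_noise_sd Hippocampal voxel noise SD.
#' @param voxels_per_location V1 voxels per retinotopic subpopulation.
#' @param hippocampus_voxels Hippocampal ROI size.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(generative_model = c("SR", "CO", "H0"),
                         gamma = 0.3, omega = 0.2,
                         stimulus_amplitude = 1, noise_sd = 2,
                         spatial_spread = 1,
                         hippocampus_tuning = list(type = "temporal",
                                                   intercept = 0.6,
                                                   slope = -0.15),
                         hippocampus_amplitude = 0.03,
                         hippocampus_noise_sd = 1,
                         voxels_per_location = 8,
                         hippocampus_voxels = 64) {
  generative_model <- match.arg(generative_model)
  stopifnot(noise_sd >= 0, hippocampus_noise_sd >= 0,
            is.finite(stimulus_amplitude), voxels_per_location >= 1,
            hippocampus_voxels >= 1)
  if (!hippocampus_tuning$type %in% c("temporal", "spatial", "none"))
    stop("hippocampus_tuning$type must be temporal, spatial or none")
  if (is.null(hippocampus_tuning$intercept) ||
      is.null(hippocampus_tuning$slope)) {
    # per-type defaults chosen so weights at the realized distances span
    # roughly 0.15-0.45
    hippocampus_tuning <- switch(hippocampus_tuning$type,
      temporal = list(type = "temporal", intercept = 0.6, slope = -0.15),
      spatial = list(type = "spatial", intercept = 1.1745, slope = -0.0732),
      none = list(type = "none", intercept = 0, slope = 0)
    )
  }
  structure(
    list(
      generative_model = generative_model, gamma = gamma, omega = omega,
      stimulus_amplitude = stimulus_amplitude, noise_sd = noise_sd,
      spatial_spread = spatial_spread,
      hippocampus_tuning = hippocampus_tuning,
      hippocampus_amplitude = hippocampus_amplitude,
      hippocampus_noise_sd = hippocampus_noise_sd,
      voxels_per_location = as.integer(voxels_per_location),
      hippocampus_voxels = as.integer(hippocampus_voxels)
    ),
    class = "ground_truth"
  )
}

# 4x4 matrix of anticipatory amplitudes per partial-trial type (rows) and
# sequence position (cols), diagonal 1 (bottom-up), in units of
# stimulus_amplitude
partial_amplitude_matrix <- function(truth) {
  m <- switch(truth$generative_model,
    SR = successor_matrix(build_transition_matrix(), truth$gamma),
    CO = {
      x <- matrix(truth$omega, 4, 4)
      diag(x) <- 1
      x
    },
    H0 = diag(4)
  )
  dimnames(m) <- list(SEQ_LABELS, SEQ_LABELS)
  m
}

# Gaussian cross-location bleed matrix (8x8), diagonal 1
bleed_matrix <- function(layout, spread) {
  n <- n_locations(layout)
  d <- outer(seq_len(n), seq_len(n),
             function(i, j) chord_distance(layout, i, j))
  exp(-d^2 / (2 * spread^2))
}

# pattern-mixing weight matrix (8x8) for hippocampal location patterns:
# identity plus tuned coactivation weights among sequence locations
hippocampus_pattern_weights <- function(truth, spec, layout) {
  W <- diag(n_locations(layout))
  tun <- truth$hippocampus_tuning
  if (tun$type == "none") return(W)
  idx <- spec$sequence_indices
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      x <- switch(tun$type,
        temporal = abs(j - i),
        spatial = chord_distance(layout, idx[i], idx[j])
      )
      W[idx[i], idx[j]] <- max(0, tun$intercept + tun$slope * x)
    }
  }
  W
}

# noiseless times x L response matrix for impulse events at `onsets` with
# per-event, per-location amplitudes `amp` (events x L); times sorted
event_response_matrix <- function(times, onsets, amp,
                                  type = "double", t_support = 32) {
  out <- matrix(0, length(times), ncol(amp))
  fi <- findInterval(onsets, times)
  for (k in seq_along(onsets)) {
    i0 <- fi[k] + 1
    if (i0 > length(times)) next
    i1 <- findInterval(onsets[k] + t_support, times)
    if (i1 < i0) next
    idx <- i0:i1
    h <- canonical_hrf(times[idx] - onsets[k], type = type)
    for (l in which(amp[k, ] != 0))
      out[idx, l] <- out[idx, l] + amp[k, l] * h
  }
  out
}

# per-trial x 8-location bottom-up + anticipatory amplitude matrix
trial_amplitude_matrix <- function(events, spec, truth, layout) {
  n <- nrow(events)
  seq_idx <- spec$sequence_indices
  A <- truth$stimulus_amplitude
  m <- partial_amplitude_matrix(truth)
  B <- bleed_matrix(layout, truth$spatial_spread)
  drive <- matrix(0, n, n_locations(layout))   # bottom-up stimulation
  antic <- matrix(0, n, n_locations(layout))   # model-generated anticipation
  full <- events$trial_type == "full"
  drive[full, seq_idx] <- A
  for (s in 1:4) {
    rows <- events$trial_type == paste0("partial_", SEQ_LABELS[s])
    if (!any(rows)) next
    drive[rows, seq_idx[s]] <- A
    for (j in setdiff(1:4, s))
      antic[rows, seq_idx[j]] <- A * m[s, j]
  }
  drive %*% B + antic
}

volume_times <- function(duration_s, tr) {
  (seq_len(ceiling(duration_s / tr)) - 1) * tr
}

voxel_series <- function(signal_by_loc, loading, noise_sd) {
  # signal_by_loc: times x L; loading: L x V; returns V x times plus noise
  s <- t(signal_by_loc %*% loading)
  if (noise_sd > 0)
    s <- s + matrix(stats::rnorm(length(s), sd = noise_sd),
                    nrow(s), ncol(s))
  s
}

#' Simulate a subject's main-task voxel time series
#'
#' V1: eight retinotopic subpopulations; full trials drive the four sequence
#' locations at `stimulus_amplitude` with Gaussian cross-location bleed;
#' partial trials drive the shown location plus anticipatory activity at the
#' omitted sequence locations given by the generative model (SR row of M, CO
#' constant omega, H0 zeros). Hippocampus: each location has a random voxel
#' pattern, mixed across sequence locations per the configured tuning; each
#' trial evokes the patterns of its driven locations. One impulse per trial
#' per driven location at trial onset, convolved with the canonical HRF,
#' sampled at TR, plus white Gaussian noise.
#'
#' @param design A [build_session()] design.
#' @param truth A [ground_truth()].
#' @param layout Stimulus layout.
#' @param seed Optional integer seed.
#' @return A `subject_data` list with `v1` and `hippocampus` series (each
#'   `values` voxels x volumes, `run`, `times`, `tr`, and for V1
#'   `voxel_location`), the hippocampal `patterns` (8 x voxels), `design`,
#'   `truth`, `layout`.
#' @export
simulate_subject <- function(design, truth, layout = build_layout(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- design$spec
  tr <- design$tr
  V1 <- truth$voxels_per_location * n_locations(layout)
  loading_v1 <- matrix(0, n_locations(layout), V1)
  voxel_location <- rep(seq_len(n_locations(layout)),
                        each = truth$voxels_per_location)
  loading_v1[cbind(voxel_location, seq_len(V1))] <- 1
  G <- matrix(stats::rnorm(n_locations(layout) * truth$hippocampus_voxels),
              n_locations(layout), truth$hippocampus_voxels)
  P <- hippocampus_pattern_weights(truth, spec, layout) %*% G

  runs <- sort(unique(design$events$run))
  v1_list <- list(); hip_list <- list(); run_id <- integer(0); tt <- numeric(0)
  for (r in runs) {
    ev <- design$events[design$events$run == r, ]
    times <- volume_times(design$run_duration_s[r], tr)
    amp <- trial_amplitude_matrix(ev, spec, truth, layout)
    S <- event_response_matrix(times, ev$onset_s, amp)
    v1_list[[r]] <- voxel_series(S, loading_v1, truth$noise_sd)
    # hippocampus: driven location amplitudes without retinotopic bleed
    amp_h <- trial_amplitude_matrix(ev, spec,
                                    within_truth_no_bleed(truth), layout)
    Sh <- event_response_matrix(times, ev$onset_s, amp_h)
    hip_list[[r]] <- voxel_series(Sh, truth$hippocampus_amplitude * P,
                                  truth$hippocampus_noise_sd)
    run_id <- c(run_id, rep(r, length(times)))
    tt <- c(tt, times)
  }
  structure(
    list(
      v1 = list(values = do.call(cbind, v1_list), run = run_id, times = tt,
                tr = tr, voxel_location = voxel_location),
      hippocampus = list(values = do.call(cbind, hip_list), run = run_id,
                         times = tt, tr = tr),
      patterns = P, design = design, truth = truth, layout = layout
    ),
    class = "subject_data"
  )
}

within_truth_no_bleed <- function(truth) {
  truth$spatial_spread <- 1e-6
  truth
}

#' Simulate a subject's localizer voxel time series
#'
#' Stimulation blocks are 13.5 s boxcars convolved with the canonical HRF.
#' V1 responds with retinotopic spatial bleed only; hippocampal responses
#' use the tuned location patterns, so coactivation of sequence-mates is
#' present when the tuning is not "none".
#'
#' @param truth A [ground_truth()].
#' @param schedule A [build_localizer_schedule()].
#' @param spec Sequence spec (defines which locations are sequence-mates).
#' @param layout Stimulus layout.
#' @param seed Optional integer seed.
#' @return A `localizer_data` list with `v1`, `hippocampus`, `patterns`,
#'   `schedule`, `truth`.
#' @export
simulate_localizer <- function(truth, schedule, spec,
                               layout = build_layout(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- schedule$blocks[!schedule$blocks$rest, ]
  times <- volume_times(schedule$total_duration_s, schedule$tr)
  nL <- n_locations(layout)
  S <- matrix(0, length(times), nL)
  for (l in seq_len(nL)) {
    b <- blocks[blocks$location == l, ]
    S[, l] <- hrf_response(times, b$onset_s,
                           amplitudes = truth$stimulus_amplitude,
                           durations = b$duration_s)
  }
  V1 <- truth$voxels_per_location * nL
  voxel_location <- rep(seq_len(nL), each = truth$voxels_per_location)
  loading_v1 <- matrix(0, nL, V1)
  loading_v1[cbind(voxel_location, seq_len(V1))] <- 1
  B <- bleed_matrix(layout, truth$spatial_spread)
  G <- matrix(stats::rnorm(nL * truth$hippocampus_voxels),
              nL, truth$hippocampus_voxels)
  P <- hippocampus_pattern_weights(truth, spec, layout) %*% G
  structure(
    list(
      v1 = list(values = voxel_series(S %*% B, loading_v1, truth$noise_sd),
                run = rep(1L, length(times)), times = times,
                tr = schedule$tr, voxel_location = voxel_location),
      hippocampus = list(
        values = voxel_series(S, truth$hippocampus_amplitude * P,
                              truth$hippocampus_noise_sd),
        run = rep(1L, length(times)), times = times, tr = schedule$tr
      ),
      patterns = P, schedule = schedule, truth = truth, spec = spec,
      layout = layout
    ),
    class = "localizer_data"
  )
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %%
               2147483647) + 1L
}

#' Assemble a synthetic cohort
#'
#' Assigns each subject a starting location, counterbalanced in frequency
#' across the eight constrained sequences, and a deterministic per-subject
#' seed derived from the cohort seed. Subject data are realized lazily with
#' [simulate_subject()] / [simulate_localizer()] via the stored descriptors.
#'
#' @param n_subjects Cohort size (default 35).
#' @param truth A [ground_truth()] template shared by all subjects.
#' @param seed Cohort seed (mandatory).
#' @param layout Stimulus layout.
#' @param n_runs Main-task runs per subject.
#' @return A `synthetic_cohort` list with `subjects` (each: `id`, `seed`,
#'   `start`, `spec`), `truth`, `layout`, `n_runs`, `seed`.
#' @export
make_cohort <- function(n_subjects = 35, truth = ground_truth(), seed,
                        layout = build_layout(), n_runs = 3) {
  if (missing(seed)) stop("`seed` is mandatory for cohort simulation")
  if (n_subjects < 2) stop("need n_subjects >= 2")
  set.seed(seed)
  specs <- enumerate_sequences(layout)
  starts <- sample(rep_len(seq_len(8), n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    list(id = i, seed = derive_seed(seed, i), start = starts[i],
         spec = specs[[starts[i]]])
  })
  structure(
    list(subjects = subjects, truth = truth, layout = layout,
         n_runs = n_runs, seed = seed),
    class = "synthetic_cohort"
  )
}

#' Realize one cohort subject's session and main-task data
#'
#' @param cohort A [make_cohort()] object.
#' @param i Subject index.
#' @return A `subject_data` as from [simulate_subject()].
#' @export
realize_subject <- function(cohort, i) {
  sub <- cohort$subjects[[i]]
  design <- build_session(sub$spec, n_runs = cohort$n_runs, seed = sub$seed)
  simulate_subject(design, cohort$truth, cohort$layout,
                   seed = derive_seed(sub$seed, 1))
}

#' Realize one cohort subject's localizer data
#'
#' @param cohort A [make_cohort()] object.
#' @param i Subject index.
#' @return A `localizer_data` as from [simulate_localizer()].
#' @export
realize_localizer <- function(cohort, i) {
  sub <- cohort$subjects[[i]]
  schedule <- build_localizer_schedule(cohort$layout,
                                       seed = derive_seed(sub$seed, 2))
  simulate_localizer(cohort$truth, schedule, sub$spec, cohort$layout,
                     seed = derive_seed(sub$seed, 3))
}
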