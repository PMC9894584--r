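# Session and localizer schedule generation: trial interleaving under the
# adjacency constraints, truncated-exponential ITIs, onset accumulation.

# trial/stimulus timing constants (seconds)
DOT_DURATION <- 0.100
DOT_ISI <- 0.017
DOT_ISI_DELAYED <- 0.170
TR_DEFAULT <- 1.5

full_trial_duration <- function(delayed = FALSE) {
  # four 100 ms dots, three ISIs; the delayed variant lengthens the last ISI
  4 * DOT_DURATION + 2 * DOT_ISI + ifelse(delayed, DOT_ISI_DELAYED, DOT_ISI)
}

#' Mean of a shifted truncated exponential
#'
#' Closed-form mean of an exponential of scale `beta` shifted to start at
#' `minimum` and truncated at `maximum`.
#' @keywords internal
truncexp_mean <- function(beta, minimum, maximum) {
  w <- maximum - minimum
  minimum + beta - w / (exp(w / beta) - 1)
}

#' Calibrate the inter-trial-interval scale
#'
#' Finds the exponential scale beta such that a shifted, truncated
#' exponential on \[minimum, maximum\] has the requested mean. The feasible
#' mean range is (minimum, (minimum + maximum) / 2): the truncated law's
#' mean approaches the midpoint as beta grows without bound.
#'
#' @param minimum,maximum Truncation bounds in seconds.
#' @param target_mean Desired mean ITI in seconds.
#' @return The scale beta in seconds, accurate to 1e-9.
#' @export
calibrate_iti_scale <- function(minimum = 2, maximum = 10.9,
                                target_mean = 3.72) {
  if (!(minimum < maximum)) stop("`minimum` must be below `maximum`")
  if (target_mean <= minimum || target_mean >= (minimum + maximum) / 2)
    stop("no solution: `target_mean` outside (minimum, (minimum+maximum)/2)")
  f <- function(b) truncexp_mean(b, minimum, maximum) - target_mean
  stats::uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-12)$root
}

#' Draw inter-trial intervals
#'
#' Inverse-CDF sampling from the truncated exponential on
#' \[minimum, maximum\] with the given scale. Uses R's current RNG state,
#' so call [set.seed()] for reproducibility.
#'
#' @param n Number of draws.
#' @param minimum,maximum Truncation bounds in seconds.
#' @param scale Exponential scale beta from [calibrate_iti_scale()].
#' @return Numeric vector of `n` ITIs in seconds.
#' @export
sample_itis <- function(n, minimum = 2, maximum = 10.9,
                        scale = calibrate_iti_scale(minimum, maximum)) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  if (scale <= 0) stop("`scale` must be positive")
  u <- stats::runif(n)
  p_max <- 1 - exp(-(maximum - minimum) / scale)
  minimum - scale * log(1 - u * p_max)
}

#' Build a main-task session design
#'
#' Generates `n_runs` runs of 192 trials: 128 full-sequence trials (52 of
#' them with a delayed last dot) and 64 partial trials, 16 per partial type
#' (one per sequence item). Every partial trial is immediately preceded and
#' followed by a full trial; this is sampled uniformly over the constrained
#' orders by placing the 64 partial trials in 64 of the 127 internal gaps
#' between consecutive full trials. Onsets accumulate trial duration plus a
#' truncated-exponential ITI from t = 0.
#'
#' @param spec A `sequence_spec` from [enumerate_sequences()].
#' @param n_runs Number of runs (default 3).
#' @param seed Optional integer seed.
#' @param n_full,n_partial_per_type,n_delayed Per-run trial counts.
#' @param iti_min,iti_max,iti_mean ITI distribution parameters (seconds).
#' @param tr Repetition time in seconds.
#' @return A `session_design` object: `events` data frame (run, trial_index,
#'   trial_type, delayed, onset_s, duration_s, iti_s), plus `spec`, `tr`,
#'   `run_duration_s`.
#' @export
build_session <- function(spec, n_runs = 3, seed = NULL,
                          n_full = 128, n_partial_per_type = 16,
                          n_delayed = 52,
                          iti_min = 2, iti_max = 10.9, iti_mean = 3.72,
                          tr = TR_DEFAULT) {
  if (!inherits(spec, "sequence_spec")) stop("`spec` must be a sequence_spec")
  if (!is.null(seed)) set.seed(seed)
  n_partial <- 4 * n_partial_per_type
  if (n_partial > n_full - 1)
    stop("too many partial trials for the adjacency constraint")
  scale <- calibrate_iti_scale(iti_min, iti_max, iti_mean)
  partial_types <- paste0("partial_", c("A", "B", "C", "D"))

  runs <- lapply(seq_len(n_runs), function(run) {
    # choose gaps between full trials (gap g sits after full trial g)
    gaps <- sort(sample.int(n_full - 1, n_partial))
    types <- sample(rep(partial_types, n_partial_per_type))
    delayed_full <- sample.int(n_full, n_delayed)
    trial_type <- character(0)
    delayed <- logical(0)
    fi <- 0
    for (g in seq_len(n_full)) {
      fi <- fi + 1
      trial_type <- c(trial_type, "full")
      delayed <- c(delayed, fi %in% delayed_full)
      k <- which(gaps == g)
      if (length(k)) {
        trial_type <- c(trial_type, types[k])
        delayed <- c(delayed, FALSE)
      }
    }
    n_trials <- length(trial_type)
    duration <- ifelse(trial_type == "full",
                       full_trial_duration(delayed), DOT_DURATION)
    iti <- sample_itis(n_trials, iti_min, iti_max, scale)
    onset <- cumsum(c(0, (duration + iti)[-n_trials]))
    data.frame(
      run = run, trial_index = seq_len(n_trials), trial_type = trial_type,
      delayed = delayed, onset_s = onset, duration_s = duration, iti_s = iti,
      stringsAsFactors = FALSE
    )
  })
  events <- do.call(rbind, runs)
  run_dur <- vapply(runs, function(r) {
    last <- nrow(r)
    r$onset_s[last] + r$duration_s[last] + r$iti_s[last]
  }, numeric(1))
  structure(
    list(events = events, spec = spec, tr = tr, run_duration_s = run_dur),
    class = "session_design"
  )
}

#' Build the functional localizer schedule
#'
#' Eight cycles; each cycle flashes the eight dot locations once in
#' pseudo-random order (13.5 s blocks) and ends with a 15 s rest. The eight
#' cycle-initial blocks — each following a rest period (the pre-run baseline
#' for cycle 1) — cover each location exactly once.
#'
#' @param layout An 8-location [build_layout()] object.
#' @param seed Optional integer seed.
#' @param block_s Stimulation block duration (default 13.5 s).
#' @param rest_s Rest duration after each cycle (default 15 s).
#' @param n_cycles Number of cycles (default 8).
#' @param tr Repetition time in seconds.
#' @return A `localizer_schedule` object with a `blocks` data frame
#'   (block_index, cycle, location, onset_s, duration_s, rest flag) and
#'   `total_duration_s`.
#' @export
build_localizer_schedule <- function(layout, seed = NULL, block_s = 13.5,
                                     rest_s = 15, n_cycles = 8,
                                     tr = TR_DEFAULT) {
  n <- n_locations(layout)
  if (n != 8) stop("localizer schedule is defined for 8-location layouts")
  if (!is.null(seed)) set.seed(seed)
  # the cycle-initial (post-rest) locations form a random permutation
  heads <- sample.int(n)
  onset <- 0
  rows <- list()
  bi <- 0
  for (cy in seq_len(n_cycles)) {
    order_rest <- sample(setdiff(seq_len(n), heads[cy]))
    for (loc in c(heads[cy], order_rest)) {
      bi <- bi + 1
      rows[[length(rows) + 1]] <- data.frame(
        block_index = bi, cycle = cy, location = loc,
        onset_s = onset, duration_s = block_s, rest = FALSE
      )
      onset <- onset + block_s
    }
    rows[[length(rows) + 1]] <- data.frame(
      block_index = NA_integer_, cycle = cy, location = NA_integer_,
      onset_s = onset, duration_s = rest_s, rest = TRUE
    )
    onset <- onset + rest_s
  }
  blocks <- do.call(rbind, rows)
  structure(
    list(blocks = blocks, tr = tr, total_duration_s = onset),
    class = "localizer_schedule"
  )
}
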