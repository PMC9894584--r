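# Hemodynamic response functions and linear-systems helpers used by both the
# simulator and the GLM design matrix.

#' Canonical hemodynamic response function
#'
#' Double-gamma HRF (peak delay 6 s, undershoot delay 16 s, undershoot ratio
#' 1/6, unit dispersions) normalized to unit peak, or a single-gamma variant
#' (peak delay 6, i.e. gamma shape 6, rate 1; mode at 5 s) for GLM bases.
#' Zero for t <= 0.
#'
#' @param t Time in seconds (vectorized).
#' @param type "double" (default) or "single".
#' @param peak_delay,undershoot_delay Gamma shape parameters (rate 1).
#' @param undershoot_ratio Relative undershoot amplitude (double only).
#' @return HRF amplitude at `t`, unit peak.
#' @export
canonical_hrf <- function(t, type = c("double", "single"),
                          peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  type <- match.arg(type)
  raw <- function(tt) {
    out <- numeric(length(tt))
    pos <- tt > 0
    h <- stats::dgamma(tt[pos], shape = peak_delay, rate = 1)
    if (type == "double")
      h <- h - undershoot_ratio *
        stats::dgamma(tt[pos], shape = undershoot_delay, rate = 1)
    out[pos] <- h
    out
  }
  default_shape <- peak_delay == 6 && undershoot_delay == 16 &&
    undershoot_ratio == 1 / 6
  key <- if (default_shape) type
         else paste(type, peak_delay, undershoot_delay, undershoot_ratio)
  peak <- hrf_peak_cache(key, raw)
  raw(t) / peak$max
}

# cache of (max value, argmax) per HRF parameterization, on a 1 ms grid
.hrf_cache <- new.env(parent = emptyenv())
hrf_peak_cache <- function(key, raw) {
  if (is.null(.hrf_cache[[key]])) {
    grid <- seq(0.001, 30, by = 0.001)
    v <- raw(grid)
    .hrf_cache[[key]] <- list(max = max(v), argmax = grid[which.max(v)])
  }
  .hrf_cache[[key]]
}

#' Time-to-peak of the canonical HRF
#'
#' Argmax of the HRF on a 1 ms grid.
#' @inheritParams canonical_hrf
#' @return Peak time in seconds.
#' @export
hrf_time_to_peak <- function(type = c("double", "single"),
                             peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  type <- match.arg(type)
  raw <- function(tt) {
    h <- stats::dgamma(tt, shape = peak_delay, rate = 1)
    if (type == "double")
      h <- h - undershoot_ratio *
        stats::dgamma(tt, shape = undershoot_delay, rate = 1)
    h
  }
  default_shape <- peak_delay == 6 && undershoot_delay == 16 &&
    undershoot_ratio == 1 / 6
  key <- if (default_shape) type
         else paste(type, peak_delay, undershoot_delay, undershoot_ratio)
  hrf_peak_cache(key, raw)$argmax
}

# cumulative integral of the unit-peak HRF on a fine grid, for boxcars
hrf_cumulative <- function(type, dt = 0.01, t_max = 40) {
  grid <- seq(0, t_max, by = dt)
  h <- canonical_hrf(grid, type = type)
  list(grid = grid, H = cumsum(h) * dt, t_max = t_max)
}

#' Expected BOLD response of an event train
#'
#' Evaluates the noiseless response at the sampling times: impulse events
#' (duration 0) contribute `amplitude * hrf(t - onset)` exactly; boxcar
#' events contribute the integrated HRF over the overlap, via a tabulated
#' cumulative HRF.
#'
#' The HRF is treated as supported on (0, `t_support`\] seconds; both the
#' simulator and the GLM design matrix use this function, so the truncation
#' is consistent throughout.
#'
#' @param times Sampling times in seconds (e.g. volume acquisition times).
#' @param onsets,amplitudes,durations Event train (recycled durations allowed).
#' @param type HRF variant ("double" or "single").
#' @param t_support Impulse-response support in seconds.
#' @return Numeric response at `times`.
#' @export
hrf_response <- function(times, onsets, amplitudes = 1, durations = 0,
                         type = c("double", "single"), t_support = 32) {
  type <- match.arg(type)
  n_ev <- length(onsets)
  amplitudes <- rep_len(amplitudes, n_ev)
  durations <- rep_len(durations, n_ev)
  out <- numeric(length(times))
  box <- durations > 0
  if (any(!box)) {
    sorted <- !is.unsorted(times)
    fi <- if (sorted) findInterval(onsets, times)
    for (k in which(!box)) {
      if (sorted) {
        # restrict to the HRF support window
        i0 <- fi[k] + 1
        i1 <- findInterval(onsets[k] + t_support, times)
        if (i0 > i1) next
        idx <- i0:i1
        out[idx] <- out[idx] +
          amplitudes[k] * canonical_hrf(times[idx] - onsets[k], type = type)
      } else {
        dt <- times - onsets[k]
        h <- canonical_hrf(dt, type = type)
        h[dt > t_support] <- 0
        out <- out + amplitudes[k] * h
      }
    }
  }
  if (any(box)) {
    cum <- hrf_cumulative(type)
    lookup <- function(tt) {
      tt <- pmin(pmax(tt, 0), cum$t_max)
      stats::approx(cum$grid, cum$H, xout = tt, rule = 2)$y
    }
    for (k in which(box)) {
      dt <- times - onsets[k]
      out <- out + amplitudes[k] * (lookup(dt) - lookup(dt - durations[k]))
    }
  }
  out
}
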