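# Hippocampal pathway: Savitzky-Golay preprocessing, multinomial logistic
# location decoding, successor/predecessor evidence contrasts, time-resolved
# evidence and HRF time-to-peak estimation.

#' Preprocess a voxel time series for decoding
#'
#' Per voxel, per run: low-pass filtering with a Savitzky-Golay filter
#' (window 5 TRs, polynomial order 3) followed by z-scoring. Constant voxels
#' get all-zero z-scores with a warning.
#'
#' @param ts A series list with `values` (voxels x volumes), `run`, `times`,
#'   `tr` (as produced by the simulator).
#' @param window Filter window length in volumes (odd, default 5).
#' @param order Polynomial order (default 3).
#' @return The same series list with filtered, z-scored `values` and a
#'   `provenance` record.
#' @export
preprocess <- function(ts, window = 5, order = 3) {
  vals <- ts$values
  runs <- unique(ts$run)
  # one Savitzky-Golay projection matrix for all voxels: the centre row is a
  # symmetric FIR filter for interior samples, the outer rows handle the
  # run edges (same scheme as signal::sgolayfilt)
  F_ <- signal::sgolay(p = order, n = window)
  half <- (window - 1) / 2
  warned <- FALSE
  for (r in runs) {
    idx <- which(ts$run == r)
    nc <- length(idx)
    if (nc < window) stop("run shorter than the filter window")
    X <- vals[, idx, drop = FALSE]
    Y <- t(stats::filter(t(X), F_[half + 1, ], sides = 2))
    Y[, seq_len(half)] <-
      X[, seq_len(window), drop = FALSE] %*% t(F_[seq_len(half), ,
                                                  drop = FALSE])
    Y[, (nc - half + 1):nc] <-
      X[, (nc - window + 1):nc, drop = FALSE] %*% t(F_[(half + 2):window, ,
                                                       drop = FALSE])
    m <- rowMeans(Y)
    s <- sqrt(rowSums((Y - m)^2) / (nc - 1))
    # constant traces can come back with ~1e-16 filter jitter
    const <- s <= 1e-10 * (abs(m) + 1)
    if (any(const) && !warned) {
      warning("constant voxel(s): z-scores set to 0")
      warned <- TRUE
    }
    vals[, idx] <- (Y - m) / ifelse(const, Inf, s)
  }
  ts$values <- vals
  ts$provenance <- list(filter = "savitzky-golay", window = window,
                        order = order, zscored = "per voxel per run")
  ts
}

#' Extract trial-locked feature samples
#'
#' For each trial, averages the volumes whose acquisition times fall within
#' `[onset + window[1], onset + window[2]]` (inclusive). At TR 1.5 s and
#' grid-aligned onsets, the localizer window (3, 13.5) covers 8 volumes and
#' the main-task window (3, 6) covers 3.
#'
#' @param ts Preprocessed series list.
#' @param onsets Trial onsets in seconds (same clock as `ts$times`).
#' @param runs Run index per trial (matched against `ts$run`).
#' @param labels Class labels per trial (location index or condition).
#' @param window Length-2 numeric: averaging window in seconds, inclusive.
#' @return A `trial_samples` list: `features` (trials x voxels), `labels`,
#'   `window`.
#' @export
extract_trial_samples <- function(ts, onsets, runs, labels,
                                  window = c(3, 13.5)) {
  if (window[2] < window[1] || window[1] < 0)
    stop("need window end >= start >= 0")
  feats <- matrix(NA_real_, length(onsets), nrow(ts$values))
  for (k in seq_along(onsets)) {
    off <- ts$times - onsets[k]
    sel <- ts$run == runs[k] & off >= window[1] - 1e-9 &
      off <= window[2] + 1e-9
    if (!any(sel)) stop("window contains no volume for trial ", k)
    feats[k, ] <- rowMeans(ts$values[, sel, drop = FALSE])
  }
  structure(list(features = feats, labels = labels, window = window),
            class = "trial_samples")
}

decoder_lambda <- function(n, C = 1) 1 / (n * C)

#' Train the multinomial location decoder
#'
#' L2-regularized multinomial logistic regression (ridge) with
#' inverse-regularization C = 1, i.e. glmnet alpha = 0 at
#' lambda = 1 / (n C), unstandardized — the common scikit-learn
#' parameterization of "logistic regression, L2, C = 1".
#'
#' @param samples A [extract_trial_samples()] object.
#' @param C Inverse regularization strength.
#' @return A `decoder_model` list: `fit` (glmnet), `classes`, `lambda`.
#' @export
train_decoder <- function(samples, C = 1) {
  y <- factor(samples$labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  lam <- decoder_lambda(nrow(samples$features), C)
  # glmnet warns about classes with < 8 observations (routine for
  # leave-one-out splits of a balanced 8-class localizer); not actionable.
  # A short warm-start path down to the target lambda avoids the solver's
  # occasional failure on a single user-supplied lambda.
  fit <- suppressWarnings(
    glmnet::glmnet(samples$features, y, family = "multinomial",
                   alpha = 0, lambda = lam * c(100, 10, 1),
                   standardize = FALSE, thresh = 1e-9)
  )
  # extract the weight set at the target lambda once; evidence() then only
  # needs a matrix product and a softmax
  hit <- which(abs(fit$lambda - lam) <= 1e-12 * lam)
  if (length(hit) == 1) {
    W <- vapply(fit$beta, function(m) as.numeric(m[, hit]),
                numeric(ncol(samples$features)))
    b <- fit$a0[, hit]
  } else {
    # path terminated early: interpolate at the target lambda
    cf <- glmnet::coef.glmnet(fit, s = lam)
    W <- vapply(cf, function(m) as.numeric(m)[-1],
                numeric(ncol(samples$features)))
    b <- vapply(cf, function(m) as.numeric(m)[1], numeric(1))
  }
  if (is.null(dim(W))) W <- matrix(W, ncol = length(fit$beta))
  structure(list(fit = fit, classes = levels(y), lambda = lam,
                 weights = W, intercepts = b,
                 n_features = ncol(samples$features)),
            class = "decoder_model")
}

#' Classifier evidence (class probabilities)
#'
#' Softmax class probabilities of the decoder for each trial; every row sums
#' to 1.
#'
#' @param model A [train_decoder()] model.
#' @param features Trials x voxels matrix (or a `trial_samples`).
#' @return An `evidence_profile`: trials x classes probability matrix.
#' @export
evidence <- function(model, features) {
  if (inherits(features, "trial_samples")) features <- features$features
  if (ncol(features) != model$n_features)
    stop("feature dimension does not match the decoder")
  scores <- sweep(features %*% model$weights, 2, model$intercepts, "+")
  scores <- scores - apply(scores, 1, max)  # softmax, overflow-safe
  p <- exp(scores)
  p <- p / rowSums(p)
  dimnames(p) <- list(NULL, model$classes)
  p
}

#' Decoding accuracy of a model on labelled samples
#' @keywords internal
decode_accuracy <- function(model, samples) {
  p <- evidence(model, samples)
  pred <- model$classes[max.col(p, ties.method = "first")]
  mean(pred == as.character(samples$labels))
}

#' Leave-one-out cross-validated decoding accuracy
#'
#' @param samples A `trial_samples` object.
#' @param C Inverse regularization strength.
#' @return Accuracy in \[0, 1\].
#' @export
loo_cross_validate <- function(samples, C = 1) {
  n <- nrow(samples$features)
  correct <- logical(n)
  for (k in seq_len(n)) {
    train <- structure(list(features = samples$features[-k, , drop = FALSE],
                            labels = samples$labels[-k]),
                       class = "trial_samples")
    m <- train_decoder(train, C = C)
    p <- evidence(m, samples$features[k, , drop = FALSE])
    correct[k] <- m$classes[which.max(p)] == as.character(samples$labels[k])
  }
  mean(correct)
}

#' Cross-validated classifier evidence
#'
#' Splits trials into folds, trains on the remaining folds, and returns the
#' held-out evidence for every trial. `folds` may be an integer fold count
#' (trials assigned round-robin in order, e.g. leave-one-cycle-out for a
#' localizer with cycle-ordered trials), a vector of fold ids, or "loo".
#'
#' @param samples A `trial_samples` object.
#' @param folds Fold specification.
#' @param C Inverse regularization strength.
#' @return Trials x classes evidence matrix.
#' @export
cross_validated_evidence <- function(samples, folds = 8, C = 1) {
  n <- nrow(samples$features)
  fold_id <- if (identical(folds, "loo")) seq_len(n)
             else if (length(folds) == 1) rep_len(seq_len(folds), n)
             else folds
  classes <- levels(factor(samples$labels))
  out <- matrix(NA_real_, n, length(classes),
                dimnames = list(NULL, classes))
  for (f in unique(fold_id)) {
    test <- fold_id == f
    train <- structure(
      list(features = samples$features[!test, , drop = FALSE],
           labels = samples$labels[!test]),
      class = "trial_samples"
    )
    m <- train_decoder(train, C = C)
    out[test, m$classes] <- evidence(m, samples$features[test, , drop = FALSE])
  }
  out
}

#' Successor/predecessor classifier-evidence contrast
#'
#' Per partial trial: subtract the mean evidence at the four control
#' locations from the evidence at each sequence location, then average the
#' control-subtracted evidence over all successor cells (positive lag from
#' the shown item) and all predecessor cells (negative lag), across trials.
#'
#' @param ev Trials x 8 evidence matrix with columns named by location
#'   index.
#' @param shown Per-trial shown sequence position (1..4).
#' @param spec Sequence spec.
#' @return List with `successor`, `predecessor` (means across trials), and
#'   `by_lag` (named mean evidence per lag -3..3, 0 = shown item).
#' @export
evidence_contrast <- function(ev, shown, spec) {
  seq_idx <- spec$sequence_indices
  ctrl_idx <- spec$control_indices
  cols <- as.integer(colnames(ev))
  seq_cols <- match(seq_idx, cols)
  ctrl_cols <- match(ctrl_idx, cols)
  centered <- ev[, seq_cols, drop = FALSE] -
    rowMeans(ev[, ctrl_cols, drop = FALSE])
  lag_vals <- -3:3
  sums <- stats::setNames(numeric(length(lag_vals)), lag_vals)
  counts <- sums
  for (k in seq_len(nrow(centered))) {
    lags <- (1:4) - shown[k]
    for (j in 1:4) {
      key <- as.character(lags[j])
      sums[key] <- sums[key] + centered[k, j]
      counts[key] <- counts[key] + 1
    }
  }
  by_lag <- sums / pmax(counts, 1)
  by_lag[counts == 0] <- NA_real_
  all_vals <- unlist(lapply(seq_len(nrow(centered)), function(k) {
    stats::setNames(centered[k, ], (1:4) - shown[k])
  }))
  lag_all <- as.integer(names(all_vals))
  list(
    successor = mean(all_vals[lag_all > 0]),
    predecessor = mean(all_vals[lag_all < 0]),
    by_lag = by_lag
  )
}

#' Time-resolved successor-minus-predecessor evidence
#'
#' Applies a trained decoder to single volumes at trial-locked offsets 0,
#' TR, 2 TR, ... up to `max_offset`, computing the successor-minus-
#' predecessor control-subtracted evidence at each offset.
#'
#' @param model Localizer-trained decoder.
#' @param ts Preprocessed main-task series.
#' @param onsets,runs Partial-trial onsets and run ids.
#' @param shown Shown sequence position per trial (1..4).
#' @param spec Sequence spec.
#' @param max_offset Largest offset in seconds (default 13.5).
#' @return Data frame with `offset_s` and `diff_evidence`.
#' @export
time_resolved_evidence <- function(model, ts, onsets, runs, shown, spec,
                                   max_offset = 13.5) {
  offsets <- seq(0, max_offset, by = ts$tr)
  # keep only trials whose full 0..max_offset window fits inside their run
  run_end <- tapply(ts$times, ts$run, max)
  ok <- onsets + max_offset <= run_end[as.character(runs)]
  onsets <- onsets[ok]; runs <- runs[ok]; shown <- shown[ok]
  diff <- vapply(offsets, function(off) {
    # one-TR bin starting at the offset: picks the single volume acquired
    # within [onset + off, onset + off + TR) even for off-grid onsets
    samp <- extract_trial_samples(ts, onsets, runs, shown,
                                  window = c(off, off + ts$tr * (1 - 1e-9)))
    ev <- evidence(model, samp)
    colnames(ev) <- model$classes
    ec <- evidence_contrast(ev, shown, spec)
    ec$successor - ec$predecessor
  }, numeric(1))
  data.frame(offset_s = offsets, diff_evidence = diff)
}

#' Fit a canonical HRF to a time course and estimate the time to peak
#'
#' Least-squares fit of `amplitude * hrf(t - latency)` over a latency grid
#' in \[-2, 8\] s (step 10 ms, closed-form amplitude at each latency,
#' amplitude free in sign). If the best-fitting amplitude is not positive
#' the time course has no transient and `NA` is returned. Otherwise the time
#' to peak is latency plus the HRF's own dense-grid argmax.
#'
#' @param timecourse Numeric values sampled at `times`.
#' @param times Sample times in seconds (>= 5 points).
#' @param latency_bounds Latency search range in seconds.
#' @return List: `time_to_peak` (s, or NA), `amplitude`, `latency`,
#'   `no_transient` flag.
#' @export
fit_hrf_peak <- function(timecourse, times, latency_bounds = c(-2, 8)) {
  if (length(times) < 5) stop("need at least 5 time points")
  lat_grid <- seq(latency_bounds[1], latency_bounds[2], by = 0.01)
  best <- list(sse = Inf, a = 0, lat = NA_real_)
  for (lat in lat_grid) {
    h <- canonical_hrf(times - lat)
    den <- sum(h^2)
    if (den == 0) next
    a <- sum(h * timecourse) / den
    sse <- sum((timecourse - a * h)^2)
    if (sse < best$sse) best <- list(sse = sse, a = a, lat = lat)
  }
  if (!is.finite(best$lat) || best$a <= 0)
    return(list(time_to_peak = NA_real_, amplitude = best$a,
                latency = best$lat, no_transient = TRUE))
  list(time_to_peak = best$lat + hrf_time_to_peak("double"),
       amplitude = best$a, latency = best$lat, no_transient = FALSE)
}
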