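# GLM beta estimation, voxel selection, control subtraction and the
# successor/predecessor amplitude analysis (the V1 results pathway).

#' Build a GLM design matrix from an events table
#'
#' One column per condition, built by convolving the condition's events
#' (impulses for zero-duration events, boxcars otherwise) with the chosen
#' HRF basis and sampling at the volume acquisition times. Nuisance columns
#' are passed through unconvolved.
#'
#' @param events Data frame with columns `condition`, `onset_s` and
#'   optionally `duration_s` (default 0 = impulse).
#' @param times Volume acquisition times in seconds.
#' @param conditions Condition names expected in the design; a condition
#'   with no events is an error. Defaults to the conditions present.
#' @param hrf HRF basis: "single" (gamma, the beta-estimation basis) or
#'   "double".
#' @param nuisance Optional matrix of unconvolved nuisance columns.
#' @return A `design_matrix` list: `X` (volumes x regressors, named),
#'   `conditions`, `times`.
#' @export
build_design_matrix <- function(events, times,
                                conditions = unique(events$condition),
                                hrf = c("single", "double"),
                                nuisance = NULL) {
  hrf <- match.arg(hrf)
  if (!all(events$condition %in% conditions))
    stop("events contain conditions not in `conditions`")
  if (max(events$onset_s) > max(times))
    stop("events past the last volume")
  dur <- if ("duration_s" %in% names(events)) events$duration_s else 0
  cols <- lapply(conditions, function(cn) {
    sel <- events$condition == cn
    if (!any(sel)) stop("condition with no events: ", cn)
    hrf_response(times, events$onset_s[sel], amplitudes = 1,
                 durations = if (length(dur) == 1) dur else dur[sel],
                 type = hrf)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- conditions
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  structure(list(X = X, conditions = conditions, times = times),
            class = "design_matrix")
}

#' Fit a voxel-wise GLM
#'
#' Ordinary least squares per voxel, with optional contrasts. Contrast t
#' statistics use the voxel's residual variance; z statistics are obtained
#' from t through the normal quantile map.
#'
#' @param values Voxels x volumes data matrix.
#' @param design A [build_design_matrix()] object (or a bare matrix).
#' @param contrasts Optional named list of contrast vectors (length =
#'   number of regressors).
#' @return A `beta_estimates` list: `betas` (regressor x voxel), `sigma2`
#'   (residual variance per voxel), `df`, and per contrast `t` and `z`
#'   matrices (contrast x voxel).
#' @export
fit_glm <- function(values, design, contrasts = NULL) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(values) != nrow(X))
    stop("data and design have different numbers of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(values)                        # volumes x voxels
  betas <- qr.coef(qrX, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  out <- list(betas = betas, sigma2 = sigma2, df = df,
              regressors = colnames(X))
  if (!is.null(contrasts)) {
    XtXinv <- chol2inv(qr.R(qrX))
    tmat <- matrix(NA_real_, length(contrasts), ncol(Y))
    for (k in seq_along(contrasts)) {
      cv <- contrasts[[k]]
      se <- sqrt(pmax(sigma2 * drop(t(cv) %*% XtXinv %*% cv), 1e-300))
      tmat[k, ] <- drop(cv %*% betas) / se
    }
    rownames(tmat) <- names(contrasts)
    # tail-stable t -> z map: work on the small tail probability
    zmat <- sign(tmat) * -stats::qnorm(stats::pt(-abs(tmat), df))
    out$t <- tmat
    out$z <- zmat
  }
  structure(out, class = "beta_estimates")
}

#' One-vs-rest contrast vectors for the localizer conditions
#'
#' For each of the given conditions, a contrast comparing it to the mean of
#' the remaining ones; zeros elsewhere (nuisance columns).
#' @param regressors All regressor names.
#' @param conditions The condition names to contrast.
#' @return Named list of contrast vectors.
#' @export
one_vs_rest_contrasts <- function(regressors, conditions) {
  stats::setNames(lapply(conditions, function(cn) {
    cv <- numeric(length(regressors))
    cv[regressors == cn] <- 1
    others <- regressors %in% setdiff(conditions, cn)
    cv[others] <- -1 / sum(others)
    cv
  }), conditions)
}

#' Preregistered localizer voxel selection
#'
#' For each location, take the `n_top` voxels with the highest one-vs-rest
#' contrast z; remove any voxel appearing in more than one location's
#' selection from all of them; trim every set (dropping its lowest-z voxels)
#' to the minimum remaining size so all locations contribute the exact same
#' number of voxels.
#'
#' @param z Locations x voxels matrix of contrast z values (or a
#'   `beta_estimates` with a `z` field).
#' @param n_top Voxels initially selected per location (default 25).
#' @return Named list of integer voxel-index vectors, one per location, all
#'   the same length.
#' @export
select_voxels <- function(z, n_top = 25) {
  if (inherits(z, "beta_estimates")) z <- z$z
  nloc <- nrow(z)
  top <- lapply(seq_len(nloc), function(l) {
    order(z[l, ], decreasing = TRUE)[seq_len(min(n_top, ncol(z)))]
  })
  counts <- table(unlist(top))
  dup <- as.integer(names(counts)[counts > 1])
  kept <- lapply(seq_len(nloc), function(l) setdiff(top[[l]], dup))
  sizes <- lengths(kept)
  if (any(sizes == 0))
    stop("a location was left with no selective voxels")
  m <- min(sizes)
  out <- lapply(seq_len(nloc), function(l) kept[[l]][seq_len(m)])
  names(out) <- if (!is.null(rownames(z))) rownames(z)
                else paste0("loc", seq_len(nloc))
  out
}

#' Control-subtracted activity profile
#'
#' Profile cell (s, l) is the mean beta of partial-trial condition s at the
#' ROI of sequence location l, minus the mean over the four control-location
#' ROIs in the same condition.
#'
#' @param roi_betas Conditions x ROI matrix of mean betas with one row per
#'   partial condition ("partial_A".."partial_D") and one column per
#'   location ROI (all 8 locations).
#' @param spec Sequence spec mapping positions to location indices.
#' @return 4x4 `activity profile` matrix (shown item x sequence location).
#' @export
control_subtract <- function(roi_betas, spec) {
  rows <- paste0("partial_", SEQ_LABELS)
  if (!all(rows %in% rownames(roi_betas)))
    stop("missing partial-trial condition betas")
  b <- roi_betas[rows, , drop = FALSE]
  seq_b <- b[, spec$sequence_indices, drop = FALSE]
  ctrl <- rowMeans(b[, spec$control_indices, drop = FALSE])
  prof <- sweep(seq_b, 1, ctrl)
  dimnames(prof) <- list(SEQ_LABELS, SEQ_LABELS)
  prof
}

#' Successor and predecessor averages of an activity profile
#'
#' Successor mean is the mean over the 6 off-diagonal cells with positive
#' temporal distance (probed item after the shown item); predecessor mean
#' over the 6 cells with negative distance. Also returns per-lag means for
#' lags -3..+3 (0 excluded).
#'
#' @param profile 4x4 activity profile (shown item x sequence location).
#' @return List with `successor`, `predecessor`, `lags` (named vector).
#' @export
successor_predecessor_average <- function(profile) {
  lag <- lag_matrix()
  lag_means <- vapply(c(-3:-1, 1:3), function(l) mean(profile[lag == l]),
                      numeric(1))
  names(lag_means) <- c(-3:-1, 1:3)
  list(
    successor = mean(profile[lag > 0]),
    predecessor = mean(profile[lag < 0]),
    lags = lag_means
  )
}

#' Per-subject V1 analysis: GLM, ROI averaging, control subtraction
#'
#' Fits the main-task GLM (4 partial conditions + full sequence, single
#' gamma basis) per run, averages betas across runs, averages voxels within
#' each location ROI, and control-subtracts to produce the 4x4 activity
#' profile the predictive models are fitted to.
#'
#' @param sim A `subject_data` from [simulate_subject()] (or the same shape
#'   from disk).
#' @param voxel_sets Optional list of voxel indices per location (e.g. from
#'   [select_voxels()]); defaults to the simulator's known voxel labels.
#' @return 4x4 activity profile.
#' @export
analyze_subject_v1 <- function(sim, voxel_sets = NULL) {
  events <- sim$design$events
  v1 <- sim$v1
  if (is.null(voxel_sets))
    voxel_sets <- split(seq_along(v1$voxel_location), v1$voxel_location)
  conds <- c(paste0("partial_", SEQ_LABELS), "full")
  runs <- sort(unique(events$run))
  beta_sum <- NULL
  for (r in runs) {
    ev <- events[events$run == r, ]
    ev$condition <- ev$trial_type
    times <- v1$times[v1$run == r]
    dm <- build_design_matrix(ev[, c("condition", "onset_s")], times,
                              conditions = conds, hrf = "double")
    fit <- fit_glm(v1$values[, v1$run == r, drop = FALSE], dm)
    beta_sum <- if (is.null(beta_sum)) fit$betas else beta_sum + fit$betas
  }
  betas <- beta_sum / length(runs)      # regressor x voxel
  roi <- vapply(voxel_sets,
                function(vx) rowMeans(betas[, vx, drop = FALSE]),
                numeric(nrow(betas)))   # regressor x ROI
  control_subtract(roi, sim$design$spec)
}

#' Activity profiles for a whole synthetic cohort
#'
#' Streams the cohort: simulates each subject, runs the V1 pathway, keeps
#' only the 4x4 profile.
#'
#' @param cohort A [make_cohort()] object.
#' @return List of per-subject activity profiles.
#' @export
cohort_v1_profiles <- function(cohort) {
  lapply(seq_along(cohort$subjects), function(i) {
    analyze_subject_v1(realize_subject(cohort, i))
  })
}
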