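# Localizer coactivation (tuning) analysis over the four sequence locations:
# temporal, spatial, SR and no-coactivation models, fitted per subject and
# compared by RMSE/BIC.

#' Build a coactivation matrix from localizer evidence
#'
#' Cell (s, l) is the mean classifier evidence for sequence location l on
#' localizer trials stimulating sequence location s, restricted to the four
#' locations that were part of the sequence. With `baseline = "control"`
#' (used by the tuning pathway) the mean evidence over the four control
#' locations is subtracted per trial first, so a location with no learned
#' coactivation sits at 0 rather than at the softmax floor — the same
#' control-subtraction logic as the main-task analyses, and what makes the
#' no-coactivation (H0) model a meaningful baseline.
#'
#' @param ev Trials x classes evidence matrix, columns named by location
#'   index.
#' @param stimulated Per-trial stimulated location index.
#' @param spec Sequence spec.
#' @param baseline "none" for raw evidence, "control" for control-location
#'   subtraction.
#' @return 4x4 `coactivation` matrix (stimulated item x probed item,
#'   sequence order A-D).
#' @export
build_coactivation <- function(ev, stimulated, spec,
                               baseline = c("none", "control")) {
  baseline <- match.arg(baseline)
  seq_idx <- spec$sequence_indices
  cols <- match(seq_idx, as.integer(colnames(ev)))
  if (any(is.na(cols))) stop("evidence matrix lacks sequence-location columns")
  vals <- ev[, cols, drop = FALSE]
  if (baseline == "control") {
    ctrl_cols <- match(spec$control_indices, as.integer(colnames(ev)))
    vals <- vals - rowMeans(ev[, ctrl_cols, drop = FALSE])
  }
  out <- matrix(NA_real_, 4, 4, dimnames = list(SEQ_LABELS, SEQ_LABELS))
  for (s in 1:4) {
    rows <- stimulated == seq_idx[s]
    if (!any(rows)) stop("missing localizer condition for sequence item ",
                         SEQ_LABELS[s])
    out[s, ] <- colMeans(vals[rows, , drop = FALSE])
  }
  out
}

#' Tuning-model predictions
#'
#' 4x4 predicted coactivation (stimulated item x probed item):
#' * temporal: `b0 + b1 * |lag|` — linear fading with distance in sequence
#'   time, symmetric for past and future;
#' * spatial: `b0 + b1 * d` with d the chord distance in dva (0 on the
#'   diagonal);
#' * SR: `scale * gamma^lag` for lag >= 0, 0 for predecessors;
#' * H0: `amplitude` on the diagonal, 0 elsewhere.
#'
#' @param model "temporal", "spatial", "SR" or "H0".
#' @param params Named list of the model's parameters (`b0`, `b1`; or
#'   `scale`, `gamma`; or `a`).
#' @param spec Sequence spec (spatial model).
#' @param layout Stimulus layout (spatial model).
#' @return 4x4 prediction matrix.
#' @export
tuning_predictions <- function(model, params, spec = NULL,
                               layout = build_layout()) {
  lag <- lag_matrix()
  pred <- switch(model,
    temporal = params$b0 + params$b1 * abs(lag),
    spatial = {
      if (is.null(spec)) stop("spatial tuning needs a sequence spec")
      idx <- spec$sequence_indices
      d <- outer(1:4, 1:4,
                 function(i, j) chord_distance(layout, idx[i], idx[j]))
      params$b0 + params$b1 * d
    },
    SR = params$scale * ifelse(lag >= 0, params$gamma^lag, 0),
    H0 = params$a * (lag == 0),
    stop("unknown tuning model: ", model)
  )
  dimnames(pred) <- list(SEQ_LABELS, SEQ_LABELS)
  pred
}

#' Fit one tuning model to a coactivation matrix
#'
#' Least squares over all 16 cells. The linear models (temporal, spatial)
#' have closed-form slope/intercept; SR uses a gamma grid (step 0.01, local
#' refinement) with a closed-form scale; H0's amplitude is the diagonal
#' mean.
#'
#' @param coact 4x4 coactivation matrix.
#' @param model "temporal", "spatial", "SR" or "H0".
#' @param spec,layout Geometry for the spatial model.
#' @return A `tuning_fit` list: `model`, `params`, `rmse`, `rss`, `bic`,
#'   `k_params` (temporal/spatial/SR 2, H0 1), `predicted`.
#' @export
fit_tuning <- function(coact, model, spec = NULL, layout = build_layout()) {
  coact <- as.matrix(coact)
  if (!all(dim(coact) == c(4, 4)) || any(!is.finite(coact)))
    stop("`coact` must be a complete 4x4 matrix")
  y <- as.vector(coact)
  lag <- lag_matrix()
  if (model %in% c("temporal", "spatial")) {
    x <- if (model == "temporal") abs(as.vector(lag)) else {
      idx <- spec$sequence_indices
      as.vector(outer(1:4, 1:4,
                      function(i, j) chord_distance(layout, idx[i], idx[j])))
    }
    cf <- stats::lm.fit(cbind(1, x), y)$coefficients
    params <- list(b0 = unname(cf[1]), b1 = unname(cf[2]))
    k <- 2
  } else if (model == "SR") {
    sse_at <- function(g) {
      p <- as.vector(ifelse(lag >= 0, g^lag, 0))
      a <- ls_scale(p, y)
      sum((y - a * p)^2)
    }
    grid <- seq(0, 1, by = 0.01)
    sse <- vapply(grid, sse_at, numeric(1))
    g0 <- grid[which.min(sse)]
    opt <- stats::optimize(sse_at, lower = max(0, g0 - 0.01),
                           upper = min(1, g0 + 0.01), tol = 1e-10)
    g <- if (opt$objective <= min(sse)) opt$minimum else g0
    p <- as.vector(ifelse(lag >= 0, g^lag, 0))
    params <- list(scale = ls_scale(p, y), gamma = g)
    k <- 2
  } else if (model == "H0") {
    params <- list(a = mean(diag(coact)))
    k <- 1
  } else stop("unknown tuning model: ", model)
  pred <- tuning_predictions(model, params, spec = spec, layout = layout)
  rss <- sum((coact - pred)^2)
  list(model = model, params = params, rmse = sqrt(rss / 16), rss = rss,
       bic = suppressWarnings(bic(max(rss, 0), 16, k)),
       k_params = k, predicted = pred)
}

#' Group-level tuning-model comparison
#'
#' Fits the four tuning models to each subject's coactivation matrix,
#' compares model errors with pairwise paired t tests, and selects the
#' winner by lowest group-mean BIC.
#'
#' @param coacts List of per-subject 4x4 coactivation matrices.
#' @param specs Per-subject sequence specs (recycled if length 1).
#' @param layout Stimulus layout.
#' @return List: `fits` data frame, `mean_bic`, `mean_rmse`, `winner`,
#'   `tests`.
#' @export
compare_tuning <- function(coacts, specs, layout = build_layout()) {
  if (length(coacts) < 2) stop("need at least 2 subjects")
  if (inherits(specs, "sequence_spec")) specs <- list(specs)
  specs <- rep_len(specs, length(coacts))
  models <- c("temporal", "spatial", "SR", "H0")
  rows <- list()
  for (s in seq_along(coacts)) {
    for (m in models) {
      f <- fit_tuning(coacts[[s]], m, spec = specs[[s]], layout = layout)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, model = m, rmse = f$rmse, bic = f$bic
      )
    }
  }
  fits <- do.call(rbind, rows)
  mean_bic <- tapply(fits$bic, fits$model, mean)[models]
  mean_rmse <- tapply(fits$rmse, fits$model, mean)[models]
  pairs <- utils::combn(models, 2, simplify = FALSE)
  tests <- lapply(pairs, function(pr) {
    x <- fits$rmse[fits$model == pr[1]]
    y <- fits$rmse[fits$model == pr[2]]
    c(list(comparison = paste(pr, collapse = " vs ")), safe_paired_t(x, y))
  })
  list(fits = fits, mean_bic = mean_bic, mean_rmse = mean_rmse,
       winner = models[which.min(mean_bic)], tests = tests)
}
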